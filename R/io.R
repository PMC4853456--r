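# File I/O: NIfTI-1 voxel maps on the skeleton grid, subject tables (CSV),
# model serialization (JSON), and YAML run configuration.

skeleton_affine <- function() structure(diag(4), code = 2L)  # RAS+, 1 mm

skeleton_dims <- function(skeleton) apply(skeleton$coords, 2, max) + 1L

#' Write a per-voxel map as a NIfTI-1 volume on the skeleton grid
#'
#' Values are placed at the skeleton's voxel coordinates in a 1-mm isotropic
#' RAS+ volume (identity affine); background voxels are zero.
#'
#' @param map numeric vector, one value per skeleton voxel.
#' @param skeleton a `tract_skeleton`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_voxel_map <- function(map, skeleton, path) {
  stopifnot(inherits(skeleton, "tract_skeleton"))
  if (length(map) != skeleton$n_voxels)
    stop("alignment error: map length must equal skeleton voxel count")
  dims <- skeleton_dims(skeleton)
  arr <- array(0, dim = dims)
  arr[skeleton$coords + 1L] <- map
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, skeleton_affine())
  img <- RNifti::`qform<-`(img, skeleton_affine())
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a voxel map from a NIfTI-1 volume
#'
#' Without a skeleton, returns the full array and affine. With a skeleton,
#' checks the grid and affine and returns the per-voxel values in skeleton
#' voxel order.
#'
#' @param path NIfTI file path.
#' @param skeleton optional `tract_skeleton` to extract against.
#' @return numeric vector (with skeleton) or the array with attribute
#'   `"affine"`.
#' @export
read_voxel_map <- function(path, skeleton = NULL) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  arr <- as.array(img)
  if (is.null(skeleton)) {
    attr(arr, "affine") <- aff
    return(arr)
  }
  if (max(abs(aff[seq_len(3), seq_len(3)] - diag(3))) > 1e-6)
    stop("alignment error: volume affine does not match the 1-mm RAS+ ",
         "skeleton grid")
  dims <- skeleton_dims(skeleton)
  if (any(dim(arr)[1:3] < dims))
    stop("alignment error: volume is smaller than the skeleton grid")
  arr[skeleton$coords + 1L]
}

#' Write the skeleton/tract mask as NIfTI-1
#' @param skeleton a `tract_skeleton`; @param path output path.
#' @return `path`, invisibly.
#' @export
write_skeleton_mask <- function(skeleton, path) {
  write_voxel_map(rep(1, skeleton$n_voxels), skeleton, path)
}

#' Export skeleton voxels as TSV (x, y, z, index)
#' @param skeleton a `tract_skeleton`; @param path output path.
#' @return `path`, invisibly.
#' @export
write_voxel_table <- function(skeleton, path) {
  df <- data.frame(x = skeleton$coords[, 1], y = skeleton$coords[, 2],
                   z = skeleton$coords[, 3], index = seq_len(skeleton$n_voxels))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a subject table from CSV
#'
#' Required header: `id,group,age,rt_mean,errors,aggression,mania`. The
#' group column accepts +1/-1 or the aliases `athlete` (+1) and `control`
#' (-1). Schema violations are reported with the offending row.
#'
#' @param path CSV path.
#' @return data frame of subject records, row order preserved.
#' @export
read_subject_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "group", "age", "rt_mean", "errors", "aggression", "mania")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("validation error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  dup <- which(duplicated(df$id))
  if (length(dup))
    stop("validation error: duplicated id '", df$id[dup[1]], "' at row ", dup[1])
  g <- tolower(as.character(df$group))
  alias <- c("1" = 1, "+1" = 1, "-1" = -1, "athlete" = 1, "control" = -1)
  bad <- which(!g %in% names(alias))
  if (length(bad))
    stop("validation error: unknown group label '", df$group[bad[1]],
         "' at row ", bad[1])
  df$group <- unname(alias[g])
  for (v in c("age", "rt_mean", "errors", "aggression", "mania")) {
    num <- suppressWarnings(as.numeric(df[[v]]))
    bad <- which(is.na(num) & !is.na(df[[v]]))
    if (length(bad))
      stop("validation error: non-numeric value '", df[[v]][bad[1]],
           "' in column ", v, " at row ", bad[1])
    df[[v]] <- num
  }
  df
}

#' Write a cohort's subject table as CSV
#' @param cohort a `dti_cohort` (or a subject data frame); @param path output.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(cohort, path) {
  df <- if (inherits(cohort, "dti_cohort")) cohort$subjects else cohort
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a trained model to a versioned JSON file
#'
#' Stores the classifier spec, coefficients or dual state, and the
#' standardization parameters, sufficient to reproduce decision scores.
#'
#' @param model a `tract_model`; @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "tract_model"))
  payload <- list(format = "tractmvpa_model", version = 1L,
                  family = model$family, spec = unclass(model$spec),
                  scaling = model$scaling, n_features = model$n_features,
                  converged = model$converged)
  if (model$family == "svm") {
    payload$ya <- model$ya; payload$b <- model$b; payload$gamma <- model$gamma
    payload$Xtrain <- model$Xtrain
  } else {
    payload$beta0 <- model$beta0; payload$beta <- model$beta
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized model
#' @param path JSON path from [write_model()].
#' @return a `tract_model`.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "tractmvpa_model"))
    stop("not a tractmvpa model file")
  spec <- structure(p$spec, class = "classifier_spec")
  m <- list(spec = spec, family = p$family,
            scaling = list(mu = p$scaling$mu, sd = p$scaling$sd),
            n_features = p$n_features, converged = p$converged)
  if (p$family == "svm") {
    m$ya <- p$ya; m$b <- p$b; m$gamma <- p$gamma
    m$Xtrain <- as.matrix(p$Xtrain)
  } else {
    m$beta0 <- p$beta0; m$beta <- p$beta
  }
  structure(m, class = "tract_model")
}

# ---- run configuration ---------------------------------------------------

config_defaults <- function() {
  list(seed = 1,
       paths = list(input_dir = ".", output_dir = "results"),
       tract = list(n_voxels = 940, end_fraction = 0.15,
                    threshold_fraction_uf = 0.20, threshold_fraction_slf = 0.40),
       cohort = list(n_pos = 19, n_neg = 17, amplitude = 6e-5,
                     sd_subject = 2e-5, sd_voxel = 2e-5, decay = 5),
       classify = list(family = "svm", kernel = "rbf", statistic = "accuracy",
                       nested = FALSE),
       permutation = list(n_perm = 500),
       bootstrap = list(n_boot = 200),
       tfce = list(E = 0.5, H = 2),
       verbosity = 1)
}

#' Assemble a run configuration
#'
#' Defaults mirror the study where it states values (0.20/0.40 thresholds,
#' LOOCV with accuracy statistic, 19/17 group sizes, TFCE via the randomise
#' conventions); permutation and bootstrap counts default to desk scale.
#' Unknown keys are rejected (fail-fast).
#'
#' @param ... named overrides of the defaults, nested lists merged by name.
#' @return a `run_config` list.
#' @export
make_run_config <- function(...) {
  over <- list(...)
  cfg <- merge_config(config_defaults(), over, path = "")
  structure(cfg, class = "run_config")
}

merge_config <- function(base, over, path) {
  for (nm in names(over)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]], full)
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Write / read a run configuration as YAML
#'
#' The round trip is lossless; reading validates against the known key set.
#' @param config a `run_config`; @param path YAML file path.
#' @return `path` / the validated `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(make_run_config, raw)
}
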