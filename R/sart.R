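# Sustained attention to response task (SART): a go/no-go paradigm in which
# digits 1-9 appear in random order and the subject responds to every digit
# except 3. Commission errors on no-go trials and fast reaction times index
# reduced response inhibition.

#' Build a SART trial schedule
#'
#' Digits 1-9 each repeated `reps_per_digit` times in seeded random order.
#' Each digit is shown for `stim_ms` followed by an `isi_ms` inter-stimulus
#' interval, giving a constant onset-to-onset spacing. The no-go flag is set
#' exactly on digit 3. The defaults give the standard 225-trial, roughly
#' 4.3-minute task.
#'
#' @param reps_per_digit repetitions of each digit (>= 1); default 25.
#' @param stim_ms stimulus duration in ms; default 250.
#' @param isi_ms inter-stimulus interval in ms; default 900.
#' @param seed integer seed for the trial order.
#' @return An object of class `sart_schedule`: a list with a `trials` data
#'   frame (`digit`, `onset_s`, `is_no_go`), `stim_ms`, `isi_ms`, and the
#'   total scheduled `duration_s`.
#' @examples
#' sch <- make_sart_schedule(seed = 1)
#' nrow(sch$trials)          # 225
#' round(sch$duration_s / 60, 1)  # 4.3
#' @export
make_sart_schedule <- function(reps_per_digit = 25, stim_ms = 250, isi_ms = 900,
                               seed = 1) {
  if (reps_per_digit < 1) stop("reps_per_digit must be at least 1")
  if (stim_ms <= 0 || isi_ms <= 0) stop("durations must be positive")
  digits <- with_seed(seed, sample(rep(1:9, reps_per_digit)))
  n <- length(digits)
  spacing <- (stim_ms + isi_ms) / 1000
  trials <- data.frame(digit = digits,
                       onset_s = (seq_len(n) - 1) * spacing,
                       is_no_go = digits == 3L)
  structure(list(trials = trials, stim_ms = stim_ms, isi_ms = isi_ms,
                 duration_s = n * spacing),
            class = "sart_schedule")
}

#' Simulate one subject's SART performance
#'
#' A simple response model: on go trials the subject responds with probability
#' `1 - p_omission` with a Gaussian reaction time (truncated below at 100 ms);
#' on no-go trials a commission error occurs with probability `p_commission`,
#' so the expected error count is `p_commission` times the number of no-go
#' trials. Mean RT is computed over correct go responses only.
#'
#' @param schedule a `sart_schedule`.
#' @param subject list with `rt_mean` (ms), `rt_sd` (ms, >= 0),
#'   `p_commission`, `p_omission` (both in `[0, 1]`).
#' @param seed integer seed.
#' @return list with `rt_mean` (ms over correct go responses), `errors`
#'   (commission errors), `omissions` (missed go trials).
#' @export
simulate_sart <- function(schedule, subject, seed = 1) {
  stopifnot(inherits(schedule, "sart_schedule"))
  p_com <- subject$p_commission %||% 0.2
  p_om <- subject$p_omission %||% 0.02
  rt_mu <- subject$rt_mean %||% 320
  rt_sd <- subject$rt_sd %||% 40
  if (p_com < 0 || p_com > 1 || p_om < 0 || p_om > 1)
    stop("probabilities must lie in [0, 1]")
  if (rt_sd < 0) stop("rt_sd must be non-negative")
  nogo <- schedule$trials$is_no_go
  with_seed(seed, {
    errors <- sum(rbinom(sum(nogo), 1, p_com))
    responded <- rbinom(sum(!nogo), 1, 1 - p_om) == 1
    rts <- pmax(rnorm(sum(responded), rt_mu, rt_sd), 100)
    list(rt_mean = if (length(rts)) mean(rts) else NA_real_,
         errors = errors,
         omissions = sum(!responded))
  })
}
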