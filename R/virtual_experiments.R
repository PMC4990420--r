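#' Burst frequency as a function of applied current
#'
#' Emulates the depolarization protocol: the cell is simulated at each
#' applied-current level and the burst frequency of the classified
#' discharge is recorded.  Within the bursting range the cycle frequency
#' increases with depolarization; silent levels report 0 Hz.
#'
#' @param p `model_parameters`.
#' @param I_app_values applied currents, pA.
#' @param ... passed to [classify_point()] / [simulate()] (e.g.
#'   `duration_s`).
#' @param cfg a [classifier_config()].
#' @return data frame with `I_app`, `frequency_hz`, `label`.
#' @export
current_frequency_curve <- function(p, I_app_values, cfg = classifier_config(),
                                    ...) {
  rows <- lapply(I_app_values, function(ia) {
    tr <- simulate(p, I_app = ia, keep_states = FALSE, ...)
    cl <- classify_discharge(tr, cfg)
    f <- cl$burst_frequency
    data.frame(I_app = ia,
               frequency_hz = if (is.na(f)) 0 else f,
               label = cl$label)
  })
  do.call(rbind, rows)
}

#' Steady-state current-voltage curve
#'
#' Wraps [voltage_clamp_current()] over a list of step potentials
#' (default -100 to +30 mV in 10 mV steps, 500 ms steps measured at
#' 400 ms).
#'
#' @param p `model_parameters`.
#' @param V_steps step potentials, mV.
#' @param ... passed to [voltage_clamp_current()].
#' @return data frame with `V_mV` and `I_pA`.
#' @export
iv_curve <- function(p, V_steps = seq(-100, 30, by = 10), ...) {
  data.frame(V_mV = V_steps,
             I_pA = vapply(V_steps, function(v)
               voltage_clamp_current(p, v, ...), numeric(1)))
}

#' Phenotype proportions of a population, with a two-stage comparison
#'
#' Tabulates phenotype counts and proportions per stage; when two stages
#' are supplied their composition is compared with Pearson's chi-square
#' test on the stage x phenotype contingency table (no continuity
#' correction; a warning is recorded when any expected count falls below
#' 5).
#'
#' @param labels named list mapping stage tag to a character vector of
#'   per-cell phenotype labels.
#' @return object of class `population_result`: list with `counts` (stage x
#'   phenotype table), `proportions`, and for two stages `chisq`
#'   (statistic, df, p_value, expected).
#' @examples
#' population_proportions(list(
#'   E18.5 = rep(c("plateau", "mixed", "oscillatory"), c(3, 9, 23))))
#' @export
population_proportions <- function(labels) {
  if (!length(labels) || any(!vapply(labels, length, integer(1))))
    stop("every stage must contain at least one classified cell")
  phen <- sort(unique(unlist(labels)))
  counts <- t(vapply(labels, function(x) table(factor(x, levels = phen)),
                     numeric(length(phen))))
  dimnames(counts) <- list(names(labels), phen)
  props <- counts / rowSums(counts)
  out <- list(counts = counts, proportions = props, chisq = NULL)
  if (nrow(counts) == 2) {
    use <- counts[, colSums(counts) > 0, drop = FALSE]
    ct <- suppressWarnings(stats::chisq.test(use, correct = FALSE))
    out$chisq <- list(statistic = unname(ct$statistic),
                      df = unname(ct$parameter),
                      p_value = unname(ct$p.value),
                      expected = ct$expected,
                      low_expected = any(ct$expected < 5))
  }
  class(out) <- "population_result"
  out
}

#' @export
print.population_result <- function(x, ...) {
  cat("<population_result>\n")
  print(round(x$proportions * 100, 1))
  if (!is.null(x$chisq))
    cat(sprintf("chi-square = %.3f, df = %d, p = %.3g%s\n",
                x$chisq$statistic, x$chisq$df, x$chisq$p_value,
                if (x$chisq$low_expected) " (expected counts < 5 present)" else ""))
  invisible(x)
}
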