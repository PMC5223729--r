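#' Incremental net monetary benefit
#'
#' `iNMB(lambda) = lambda * (e1 - e0) - (c1 - c0)`, where strategy 1 is the
#' intervention (BNP-guided care) and strategy 0 the comparator. A positive
#' iNMB at the willingness-to-pay threshold `lambda` means the intervention
#' is cost-effective at that threshold.
#'
#' @param c0,e0 Comparator cost (GBP) and effect (QALYs).
#' @param c1,e1 Intervention cost and effect.
#' @param lambda Willingness-to-pay per QALY, >= 0 (default £20,000, the
#'   lower NICE threshold). Vectorised over `lambda` and over draws.
#' @return iNMB in GBP.
#' @examples
#' inmb(58139, 5.02, 63527, 5.57, 20000) # 5612
#' @export
inmb <- function(c0, e0, c1, e1, lambda = 20000) {
  if (any(lambda < 0)) stop("inmb(): lambda must be >= 0", call. = FALSE)
  lambda * (e1 - e0) - (c1 - c0)
}

#' Incremental cost-effectiveness ratio
#'
#' `ICER = (c1 - c0) / (e1 - e0)`. When the intervention is cheaper and
#' more effective it *dominates* the comparator; when dearer and less
#' effective it is *dominated*; in either case the ratio alone is not
#' interpretable, so the quadrant is flagged.
#'
#' @inheritParams inmb
#' @return ICER in GBP per QALY, with attribute `dominance` set to
#'   `"dominant"`, `"dominated"` or `"none"`; `NA` with attribute
#'   `undefined = TRUE` when `e1 == e0`.
#' @examples
#' icer(58139, 5.02, 63527, 5.57) # 9796.4
#' @export
icer <- function(c0, e0, c1, e1) {
  dc <- c1 - c0
  de <- e1 - e0
  if (de == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  dominance <- if (dc < 0 && de > 0) "dominant"
  else if (dc > 0 && de < 0) "dominated"
  else "none"
  structure(dc / de, dominance = dominance)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of probabilistic draws
#' with strictly positive incremental net monetary benefit.
#'
#' @param delta_cost,delta_effect Vectors of incremental cost and effect,
#'   one entry per probabilistic iteration.
#' @param lambda_grid Non-negative willingness-to-pay grid; the default
#'   covers £0–£50,000 in £500 steps (which includes £20,000).
#' @return A `ceac` data frame with columns `lambda` and `probability`.
#' @export
ceac <- function(delta_cost, delta_effect,
                 lambda_grid = seq(0, 50000, by = 500)) {
  if (length(delta_cost) == 0L) {
    stop("ceac(): no probabilistic draws supplied", call. = FALSE)
  }
  stopifnot(length(delta_cost) == length(delta_effect))
  if (any(lambda_grid < 0)) {
    stop("ceac(): lambda grid must be non-negative", call. = FALSE)
  }
  prob <- vapply(lambda_grid, function(l) {
    mean(l * delta_effect - delta_cost > 0)
  }, numeric(1))
  structure(data.frame(lambda = lambda_grid, probability = prob),
            class = c("ceac", "data.frame"))
}

#' @export
plot.ceac <- function(x, ...) {
  graphics::plot(x$lambda, x$probability, type = "l", ylim = c(0, 1),
                 xlab = "Willingness to pay (GBP per QALY)",
                 ylab = "P(cost-effective)", ...)
  graphics::abline(v = 20000, lty = 3)
  invisible(x)
}

#' Write a CEAC to a two-column text file
#'
#' @param x A [ceac] data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ceac <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Internal constructor for a deterministic cost-effectiveness result.
ce_result <- function(c0, e0, c1, e1, lambda, subgroup, scenario,
                      traces = NULL) {
  c0 <- unname(c0); e0 <- unname(e0); c1 <- unname(c1); e1 <- unname(e1)
  structure(list(
    subgroup = subgroup, scenario = scenario,
    cost_clinical = c0, qalys_clinical = e0,
    cost_bnp = c1, qalys_bnp = e1,
    delta_cost = c1 - c0, delta_qalys = e1 - e0,
    icer = icer(c0, e0, c1, e1),
    lambda = lambda,
    inmb = inmb(c0, e0, c1, e1, lambda),
    traces = traces
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result> ", x$subgroup, " / ", x$scenario, "\n", sep = "")
  cat(sprintf("  clinically guided: £%.0f, %.3f QALYs\n",
              x$cost_clinical, x$qalys_clinical))
  cat(sprintf("  BNP-guided:        £%.0f, %.3f QALYs\n",
              x$cost_bnp, x$qalys_bnp))
  cat(sprintf("  increment: £%.0f, %.4f QALYs; ICER £%.0f/QALY; iNMB(λ=%.0f) £%.0f\n",
              x$delta_cost, x$delta_qalys, as.numeric(x$icer), x$lambda,
              x$inmb))
  invisible(x)
}
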