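#' One-way sensitivity analysis for a single parameter
#'
#' Recomputes the base-case ICER with the parameter pinned at `low` and at
#' `high`, everything else held at base case.
#'
#' @param config A `model_config`.
#' @param param_id Parameter id (must exist in the config).
#' @param low,high Values to pin the parameter at; default to the parameter's
#'   configured range.
#' @return A `tornado_entry`: `param_id`, `icer_low`, `icer_high` (ICER at
#'   the low/high parameter value), `bar_width = |icer_high - icer_low|` and
#'   the base-case `icer`.
#' @examples
#' one_way(default_config(), "risk_second_line_xelox", 0.464, 0.696)
#' @export
one_way <- function(config, param_id, low = NULL, high = NULL) {
  i <- match(param_id, config$parameters$id)
  if (is.na(i)) stop("unknown parameter id: ", param_id, call. = FALSE)
  if (is.null(low)) low <- config$parameters$low[i]
  if (is.null(high)) high <- config$parameters$high[i]
  base_values <- param_values(config)
  icer_at <- function(v) {
    values <- base_values
    values[[param_id]] <- v
    bc <- run_base_case(config, values = values)
    bc$comparison$icer
  }
  icer_low <- icer_at(low)
  icer_high <- icer_at(high)
  structure(list(param_id = param_id, low = low, high = high,
                 icer_low = icer_low, icer_high = icer_high,
                 bar_width = abs(icer_high - icer_low),
                 icer = run_base_case(config)$comparison$icer),
            class = "tornado_entry")
}

#' Tornado (one-way) sensitivity analysis over all parameters
#'
#' Runs [one_way()] for every parameter with a non-degenerate range (by
#' default all 29: the 28 distribution-table rows plus the discount rate) and
#' sorts entries by descending bar width, ties broken by parameter id.
#'
#' @param config A `model_config`.
#' @param param_ids Parameter ids to vary; defaults to all in the config.
#' @return Data frame `param_id, low, high, icer_low, icer_high, bar_width`,
#'   sorted; base-case ICER in attribute `base_icer`.
#' @export
tornado <- function(config, param_ids = NULL) {
  if (is.null(param_ids)) param_ids <- config$parameters$id
  if (length(param_ids) < 1L) stop("no parameters to vary", call. = FALSE)
  base_icer <- run_base_case(config)$comparison$icer
  rows <- lapply(param_ids, function(id) {
    e <- one_way(config, id)
    data.frame(param_id = id, low = e$low, high = e$high,
               icer_low = e$icer_low, icer_high = e$icer_high,
               bar_width = e$bar_width)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$bar_width, out$param_id), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  out
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Per iteration, every uncertain parameter is redrawn jointly (independent
#' draws from its [build_sampler()] distribution), the model re-evaluated for
#' both arms, and the per-arm costs and QALYs stored. Reproducible under
#' `seed`.
#'
#' @param config A `model_config`.
#' @param n_iter Number of iterations (default from `config$psa`).
#' @param seed Integer seed (default from `config$psa`).
#' @return A `psa_result`: data frame `draws` with per-arm `cost_*`/`qaly_*`,
#'   `delta_cost`, `delta_qaly`; plus `n_iter`, `seed` and the arm labels.
#' @export
run_psa <- function(config, n_iter = NULL, seed = NULL) {
  config <- validate_config(config)
  if (is.null(n_iter)) n_iter <- config$psa$n_iter
  if (is.null(seed)) seed <- config$psa$seed
  if (n_iter < 1) stop("`n_iter` must be >= 1", call. = FALSE)
  dists <- config_distributions(config)
  set.seed(seed)
  draw_mat <- vapply(dists, function(d) {
    tryCatch(build_sampler(d)(n_iter),
             error = function(e) stop("PSA sampler failed for `", d$param_id,
                                      "`: ", conditionMessage(e),
                                      call. = FALSE))
  }, numeric(n_iter))
  if (n_iter == 1L) draw_mat <- matrix(draw_mat, nrow = 1,
                                       dimnames = list(NULL, names(dists)))
  base_values <- param_values(config)
  arms <- config$arms
  one_iter <- function(i) {
    values <- base_values
    values[colnames(draw_mat)] <- draw_mat[i, ]
    o1 <- evaluate_arm(config, arms[1], values)
    o2 <- evaluate_arm(config, arms[2], values)
    c(cost_ref = o1$cost_total, qaly_ref = o1$qaly_total,
      cost_alt = o2$cost_total, qaly_alt = o2$qaly_total,
      delta_cost = o2$cost_total - o1$cost_total,
      delta_qaly = o2$qaly_total - o1$qaly_total)
  }
  draws <- as.data.frame(t(vapply(seq_len(n_iter), one_iter, numeric(6))))
  draws$iter <- seq_len(n_iter)
  structure(list(draws = draws, n_iter = n_iter, seed = seed,
                 ref_arm = arms[1], alt_arm = arms[2]),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %d), %s vs %s\n",
              x$n_iter, x$seed, x$alt_arm, x$ref_arm))
  cat(sprintf("  mean dCost %0.2f, mean dQALY %0.4f\n",
              mean(x$draws$delta_cost), mean(x$draws$delta_qaly)))
  invisible(x)
}

#' Probability that the reference arm is cost-effective
#'
#' Fraction of PSA draws in which the reference arm has the (strictly) higher
#' net monetary benefit `NMB = wtp * QALY - cost` at the given
#' willingness-to-pay threshold.
#'
#' @param psa A [run_psa()] result.
#' @param wtp Willingness-to-pay threshold (money/QALY).
#' @return Probability in `[0, 1]`.
#' @export
prob_cost_effective <- function(psa, wtp) {
  stopifnot(inherits(psa, "psa_result"), is.numeric(wtp), wtp >= 0)
  d <- psa$draws
  nmb_ref <- wtp * d$qaly_ref - d$cost_ref
  nmb_alt <- wtp * d$qaly_alt - d$cost_alt
  mean(nmb_ref > nmb_alt)
}

#' Cost-effectiveness acceptability curve
#'
#' [prob_cost_effective()] evaluated on a grid of willingness-to-pay values;
#' in the two-strategy case the two probabilities are complementary by
#' construction.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Non-empty numeric vector of thresholds.
#' @return Data frame `wtp, prob_ref, prob_alt`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 200000, by = 10000)) {
  stopifnot(inherits(psa, "psa_result"))
  if (length(wtp_grid) < 1L) stop("empty WTP grid", call. = FALSE)
  prob_ref <- vapply(wtp_grid, function(w) prob_cost_effective(psa, w),
                     numeric(1))
  data.frame(wtp = wtp_grid, prob_ref = prob_ref, prob_alt = 1 - prob_ref)
}

#' Export sensitivity-analysis results as CSV
#'
#' `write_tornado()`: `param_id,icer_low,icer_high,bar_width` (sorted);
#' `write_psa()`: `iter,delta_cost,delta_qaly`;
#' `write_ceac()`: `wtp,prob_<ref>,prob_<alt>` with lower-cased arm labels.
#'
#' @param tornado,psa,ceac Results of [tornado()], [run_psa()], [ceac()].
#' @param path File path.
#' @return The written data frame, invisibly.
#' @export
write_tornado <- function(tornado, path) {
  df <- tornado[c("param_id", "icer_low", "icer_high", "bar_width")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname write_tornado
#' @export
write_psa <- function(psa, path) {
  stopifnot(inherits(psa, "psa_result"))
  df <- psa$draws[c("iter", "delta_cost", "delta_qaly")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname write_tornado
#' @param ref_arm,alt_arm Arm labels used in the CEAC column names.
#' @export
write_ceac <- function(ceac, path, ref_arm = "x", alt_arm = "xelox") {
  df <- ceac
  names(df) <- c("wtp", paste0("prob_", tolower(ref_arm)),
                 paste0("prob_", tolower(alt_arm)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Sensitivity-analysis figures
#'
#' `plot_tornado()` draws the sorted one-way ICER ranges as horizontal bars
#' around the base-case ICER; `plot_ce_plane()` the PSA draws on the
#' incremental cost-effectiveness plane with the WTP line; `plot_ceac()` the
#' acceptability curves of both strategies.
#'
#' @param tornado,psa,ceac Results of [tornado()], [run_psa()], [ceac()].
#' @param top Number of parameters shown in the tornado (default 10).
#' @param wtp Willingness-to-pay threshold drawn on the CE plane.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, top = 10) {
  df <- utils::head(tornado, top)
  df$param_id <- factor(df$param_id, levels = rev(df$param_id))
  base <- attr(tornado, "base_icer")
  ggplot2::ggplot(df, ggplot2::aes(y = .data$param_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$param_id),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(x = "ICER ($/QALY)", y = NULL,
                  title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_tornado
#' @export
plot_ce_plane <- function(psa, wtp = 26598) {
  stopifnot(inherits(psa, "psa_result"))
  ggplot2::ggplot(psa$draws,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, colour = "steelblue") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0) + ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost ($)",
                  title = sprintf("CE plane (%s vs %s), WTP %s",
                                  psa$alt_arm, psa$ref_arm,
                                  format(wtp, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' @rdname plot_tornado
#' @param ref_label,alt_label Legend labels for the two strategies.
#' @export
plot_ceac <- function(ceac, ref_label = "X", alt_label = "XELOX") {
  df <- rbind(
    data.frame(wtp = ceac$wtp, prob = ceac$prob_ref, strategy = ref_label),
    data.frame(wtp = ceac$wtp, prob = ceac$prob_alt, strategy = alt_label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wtp, y = .data$prob,
                                   colour = .data$strategy)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "Willingness to pay ($/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::theme_minimal()
}
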