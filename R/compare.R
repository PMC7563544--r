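#' Aggregate one participant's metrics into per-cell medians and deltas
#'
#' Medians are computed per marginal cell — forward, backward (across all
#' sensors / pairs / nodes) and performing, non-performing (across the
#' side's sensors, pooling both segments) — for each metric: node NSR of
#' angular acceleration ("nsr_aa"), pairwise-difference NSR ("nsr_aa_diff",
#' side cells use pairs whose two endpoints share that side), body-body
#' cross-correlation ("xcorr_body"), clustering coefficient ("clustering"),
#' heart-body EMD ("emd_heart"), heart-body cross-correlation
#' ("xcorr_heart") and signed heart-body lag ("lag_heart", positive = ECG
#' leads).  EMD and lag additionally get the full segment-by-side cell grid
#' for the conditional contrasts.
#'
#' @param metrics an [analyze_session()] result.
#' @param participant optional identifier stored on the rows.
#' @return object of class `intent_comparison`: list with `cells` (metric,
#'   cell, value), `grid` (metric, segment, side, value), `deltas` (metric,
#'   contrast, delta) and `n_valid_trials`.
#' @export
aggregate_metrics <- function(metrics, participant = NA_character_) {
  stopifnot(inherits(metrics, "intent_metrics"))
  med <- function(x) if (all(is.na(x))) NA_real_ else
    stats::median(x, na.rm = TRUE)

  cells <- list()
  grid <- list()
  put <- function(metric, cell, value)
    cells[[length(cells) + 1L]] <<- data.frame(metric = metric, cell = cell,
                                               value = value)
  put_grid <- function(metric, segment, side, value)
    grid[[length(grid) + 1L]] <<- data.frame(metric = metric,
                                             segment = segment, side = side,
                                             value = value)

  nn <- metrics$nsr_nodes
  for (sg in c("forward", "backward"))
    put("nsr_aa", sg, med(nn$nsr[nn$segment == sg]))
  for (sd in c("performing", "nonperforming"))
    put("nsr_aa", sd, med(nn$nsr[nn$side == sd]))

  np <- metrics$nsr_pairs
  for (sg in c("forward", "backward"))
    put("nsr_aa_diff", sg, med(np$nsr[np$segment == sg]))
  for (sd in c("performing", "nonperforming"))
    put("nsr_aa_diff", sd, med(np$nsr[np$pair_side == sd]))

  sides <- metrics$sides
  for (sg in c("forward", "backward")) {
    W <- metrics$adjacency[[sg]]$weights
    put("xcorr_body", sg, med(W[upper.tri(W)]))
  }
  for (sd in c("performing", "nonperforming")) {
    vals <- unlist(lapply(metrics$adjacency, function(a) {
      keep <- sides[a$labels] == sd
      W <- a$weights[keep, keep, drop = FALSE]
      W[upper.tri(W)]
    }))
    put("xcorr_body", sd, med(vals))
  }

  cl <- metrics$clustering
  for (sg in c("forward", "backward"))
    put("clustering", sg, med(cl$clustering[cl$segment == sg]))
  for (sd in c("performing", "nonperforming"))
    put("clustering", sd, med(cl$clustering[cl$side == sd]))

  hh <- metrics$heart
  for (mname in c("emd_heart", "xcorr_heart", "lag_heart")) {
    col <- c(emd_heart = "emd", xcorr_heart = "xcorr",
             lag_heart = "lag_s")[[mname]]
    for (sg in c("forward", "backward"))
      put(mname, sg, med(hh[[col]][hh$segment == sg]))
    for (sd in c("performing", "nonperforming"))
      put(mname, sd, med(hh[[col]][hh$side == sd]))
    for (sg in c("forward", "backward"))
      for (sd in c("performing", "nonperforming"))
        put_grid(mname, sg, sd,
                 med(hh[[col]][hh$segment == sg & hh$side == sd]))
  }

  cells <- do.call(rbind, cells)
  grid <- do.call(rbind, grid)

  dl <- list()
  for (m in unique(cells$metric)) {
    v <- function(cell) cells$value[cells$metric == m & cells$cell == cell]
    dl[[length(dl) + 1L]] <- data.frame(
      metric = m,
      contrast = c("segment", "side"),
      delta = c(v("forward") - v("backward"),
                v("performing") - v("nonperforming")))
  }
  g <- function(m, sg, sd)
    grid$value[grid$metric == m & grid$segment == sg & grid$side == sd]
  for (m in c("emd_heart", "lag_heart")) {
    dl[[length(dl) + 1L]] <- data.frame(
      metric = m,
      contrast = c("segment|performing", "segment|nonperforming",
                   "side|forward", "side|backward"),
      delta = c(g(m, "forward", "performing") - g(m, "backward", "performing"),
                g(m, "forward", "nonperforming") -
                  g(m, "backward", "nonperforming"),
                g(m, "forward", "performing") -
                  g(m, "forward", "nonperforming"),
                g(m, "backward", "performing") -
                  g(m, "backward", "nonperforming")))
  }
  deltas <- do.call(rbind, dl)

  structure(list(participant = participant, cells = cells, grid = grid,
                 deltas = deltas,
                 n_valid_trials = metrics$n_valid_trials),
            class = "intent_comparison")
}

#' @export
print.intent_comparison <- function(x, ...) {
  cat(sprintf("<intent_comparison> participant %s, %d valid trials\n",
              x$participant, x$n_valid_trials))
  print(x$cells)
  invisible(x)
}

#' Cross-participant consistency summary (o / triangle / - grid)
#'
#' For every metric and contrast the per-participant delta signs are
#' reduced to a symbol: `"o"` when the favored category is higher for every
#' participant, `"triangle"` when higher for most (strictly more than
#' half), `"-"` otherwise.  The heart-body lag rows are additionally
#' expressed as which signal leads (`EKG` for positive median lag, `LS` for
#' negative) per cell.
#'
#' @param comparisons list of [aggregate_metrics()] results (>= 2).
#' @return object of class `consistency_summary`: data.frame with `metric`,
#'   `contrast`, `favored`, `symbol`, `n_higher`, `n`; plus a `lead`
#'   data.frame (cell, leads, symbol) as an attribute-free list element.
#' @export
summarize_cohort <- function(comparisons) {
  stopifnot(length(comparisons) >= 2L,
            all(vapply(comparisons, inherits, logical(1), "intent_comparison")))
  dmat <- lapply(comparisons, function(cp) cp$deltas)
  keys <- unique(do.call(rbind, dmat)[, c("metric", "contrast")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    m <- keys$metric[i]; ct <- keys$contrast[i]
    dd <- vapply(dmat, function(d)
      d$delta[d$metric == m & d$contrast == ct][1], numeric(1))
    dd <- dd[!is.na(dd)]
    n <- length(dd)
    npos <- sum(dd > 0)
    pos_label <- if (startsWith(ct, "side")) "performing" else "forward"
    neg_label <- if (startsWith(ct, "side")) "nonperforming" else "backward"
    if (n == 0) { favored <- "none"; symbol <- "-"; nh <- 0L }
    else if (npos == n) { favored <- pos_label; symbol <- "o"; nh <- npos }
    else if (npos == 0) { favored <- neg_label; symbol <- "o"; nh <- n }
    else if (npos > n / 2) { favored <- pos_label; symbol <- "triangle"; nh <- npos }
    else if (n - npos > n / 2) { favored <- neg_label; symbol <- "triangle"
      nh <- n - npos }
    else { favored <- "none"; symbol <- "-"; nh <- max(npos, n - npos) }
    rows[[i]] <- data.frame(metric = m, contrast = ct, favored = favored,
                            symbol = symbol, n_higher = nh, n = n)
  }
  summary <- do.call(rbind, rows)

  # lead/lag per marginal cell: which signal leads, and how consistently
  lead_rows <- list()
  for (cell in c("forward", "backward", "performing", "nonperforming")) {
    lv <- vapply(comparisons, function(cp)
      cp$cells$value[cp$cells$metric == "lag_heart" & cp$cells$cell == cell][1],
      numeric(1))
    lv <- lv[!is.na(lv)]
    n <- length(lv)
    npos <- sum(lv > 0)
    leads <- if (n == 0) "none" else if (npos >= n - npos) "EKG" else "LS"
    agree <- max(npos, n - npos)
    symbol <- if (n == 0) "-" else if (agree == n) "o" else
      if (agree > n / 2) "triangle" else "-"
    lead_rows[[length(lead_rows) + 1L]] <-
      data.frame(cell = cell, leads = leads, symbol = symbol,
                 n_agree = agree, n = n)
  }
  structure(list(summary = summary, lead = do.call(rbind, lead_rows),
                 n_participants = length(comparisons)),
            class = "consistency_summary")
}

#' @export
print.consistency_summary <- function(x, ...) {
  sym <- function(m, ct) {
    r <- x$summary[x$summary$metric == m & x$summary$contrast == ct, ]
    if (!nrow(r) || r$symbol == "-") return(c("-", ""))
    lab <- c(forward = "Forward", backward = "Backward",
             performing = "Performing", nonperforming = "Non-Performing")
    c(if (r$symbol == "o") "o" else "D", lab[[r$favored]])
  }
  cat(sprintf("Consistency summary (%d participants)\n", x$n_participants))
  cat("  [o = higher for every participant, D = higher for most]\n\n")
  fmt <- "  %-28s %-12s %-18s\n"
  cat(sprintf(fmt, "metric", "segment", "side"))
  for (m in c("nsr_aa", "nsr_aa_diff", "xcorr_body", "clustering",
              "emd_heart", "xcorr_heart")) {
    a <- sym(m, "segment"); b <- sym(m, "side")
    cat(sprintf(fmt, m, paste(a[1], a[2]), paste(b[1], b[2])))
  }
  cat("\n  heart-body lead per cell:\n")
  for (i in seq_len(nrow(x$lead)))
    cat(sprintf("    %-15s %s (%s, %d/%d)\n", x$lead$cell[i], x$lead$leads[i],
                x$lead$symbol[i], x$lead$n_agree[i], x$lead$n[i]))
  invisible(x)
}

#' Optional per-metric sign test across participants
#'
#' Exact binomial test of the per-participant delta signs for one metric
#' and contrast.  Off by default in all summaries: with eight participants
#' the median-consistency symbols are the primary description.
#'
#' @param comparisons list of [aggregate_metrics()] results.
#' @param metric,contrast the cell to test.
#' @return `htest` from [stats::binom.test()].
#' @export
sign_test_deltas <- function(comparisons, metric, contrast = "segment") {
  dd <- vapply(comparisons, function(cp)
    cp$deltas$delta[cp$deltas$metric == metric &
                      cp$deltas$contrast == contrast][1], numeric(1))
  dd <- dd[!is.na(dd) & dd != 0]
  stats::binom.test(sum(dd > 0), length(dd))
}
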