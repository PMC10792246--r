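# Densitometry quantification and treatment-response calls.

#' Total-protein level relative to WT from blot densitometry
#'
#' The transporter typically runs as a doublet; both bands are quantified
#' *together* and normalized to the beta-actin band of the same lane, then
#' expressed relative to the WT lane of the same blot:
#' `100 * (sum(bands)/actin) / (sum(wt_bands)/wt_actin)`. The split between
#' the two bands never enters.
#'
#' @param bands numeric vector of 1-2 band intensities for the lane.
#' @param actin beta-actin intensity of the lane (> 0).
#' @param wt_bands,wt_actin the WT lane of the same blot.
#' @return percent of WT.
#' @examples
#' quantify_total(c(500, 300), 400, c(800, 0), 400)  # 100
#' @export
quantify_total <- function(bands, actin, wt_bands, wt_actin) {
  if (length(bands) < 1L || length(bands) > 2L ||
      length(wt_bands) < 1L || length(wt_bands) > 2L) {
    stop("expect 1-2 ABCA1 bands per lane", call. = FALSE)
  }
  if (!is.finite(actin) || actin <= 0 || !is.finite(wt_actin) ||
      wt_actin <= 0) {
    stop("actin intensity must be > 0", call. = FALSE)
  }
  wt_ratio <- sum(wt_bands) / wt_actin
  if (wt_ratio <= 0) stop("WT lane has no ABCA1 signal", call. = FALSE)
  100 * (sum(bands) / actin) / wt_ratio
}

#' Per-lane total protein for a whole blot table
#'
#' Applies [quantify_total()] within each experiment x condition group using
#' that group's WT lane; lanes are never bridged across blots.
#'
#' @param blots a `blot_table` ([simulate_blots()] or [read_blot_table()]).
#' @return data.frame of `construct`, `experiment`, `condition`,
#'   `total_pct_wt`.
#' @export
quantify_blots <- function(blots) {
  blots <- as.data.frame(blots)
  if (!"condition" %in% names(blots)) blots$condition <- "mock_treated"
  grp <- interaction(blots$experiment, blots$condition, drop = TRUE)
  res <- lapply(split(blots, grp), function(b) {
    wt <- b[b$construct == "WT", , drop = FALSE]
    if (nrow(wt) != 1L) {
      stop("need exactly one WT lane per blot (experiment ",
           b$experiment[1], ", ", b$condition[1], ")", call. = FALSE)
    }
    pct <- vapply(seq_len(nrow(b)), function(i) {
      quantify_total(c(b$band1[i], b$band2[i]), b$actin[i],
                     c(wt$band1, wt$band2), wt$actin)
    }, numeric(1))
    data.frame(construct = b$construct, experiment = b$experiment,
               condition = b$condition, total_pct_wt = pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  row.names(out) <- NULL
  out
}

#' Surface expression relative to WT, corrected for total protein
#'
#' Pull-down (surface) signal divided by the sample's measured total protein,
#' normalized to the WT ratio of the same experiment:
#' `100 * (surface/total) / (wt_surface/wt_total)`. Invariant to any common
#' rescaling of one sample's signals.
#'
#' @param surface,total the sample's surface signal (>= 0) and total level
#'   (> 0).
#' @param wt_surface,wt_total the matched WT sample.
#' @return percent of WT.
#' @export
surface_expression <- function(surface, total, wt_surface, wt_total) {
  if (!is.finite(total) || total <= 0 || !is.finite(wt_total) ||
      wt_total <= 0) {
    stop("total protein levels must be > 0", call. = FALSE)
  }
  if (surface < 0 || wt_surface < 0) {
    stop("surface signals must be >= 0", call. = FALSE)
  }
  wt_ratio <- wt_surface / wt_total
  if (wt_ratio <= 0) stop("WT sample has no surface signal", call. = FALSE)
  100 * (surface / total) / wt_ratio
}

#' Surface expression for a whole surface-assay table
#'
#' Normalization is to the *mock-treated* WT of the same experiment, so
#' treatment arms remain comparable to their mock baseline.
#'
#' @param surface a `surface_table` ([simulate_surface()] or
#'   [read_surface_table()]).
#' @return data.frame of `construct`, `experiment`, `condition`,
#'   `surface_pct_wt`.
#' @export
quantify_surface <- function(surface) {
  surface <- as.data.frame(surface)
  if (!"condition" %in% names(surface)) surface$condition <- "mock_treated"
  res <- lapply(split(surface, surface$experiment), function(s) {
    wt <- s[s$construct == "WT" & s$condition == "mock_treated", ,
            drop = FALSE]
    if (nrow(wt) != 1L) {
      stop("need exactly one mock-treated WT sample per experiment ",
           s$experiment[1], call. = FALSE)
    }
    pct <- vapply(seq_len(nrow(s)), function(i) {
      surface_expression(s$surface_signal[i], s$total_level[i],
                         wt$surface_signal, wt$total_level)
    }, numeric(1))
    data.frame(construct = s$construct, experiment = s$experiment,
               condition = s$condition, surface_pct_wt = pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  row.names(out) <- NULL
  out
}

#' Treatment-response call (rescue or stabilization)
#'
#' Fold change is the ratio of arm means (robust with small unpaired arms);
#' significance is a one-tailed [auto_t_test()] in the hypothesized
#' direction. A responder needs both `p < 0.05` and a fold change in that
#' direction — a significant effect the wrong way is not a response.
#'
#' @param treated,mock numeric vectors of per-experiment values (n >= 2
#'   each), e.g. activities or surface expressions in % of mock-treated WT.
#' @param condition label stored in the result (e.g. `"epoxomicin"`).
#' @param direction `"increase"` (default) or `"decrease"`.
#' @return a `treatment_response` list: `condition`, `fold_change`,
#'   `p_value`, `stars`, `responder`, `test`.
#' @examples
#' treatment_response(c(150, 160, 155), c(100, 95, 105))
#' @export
treatment_response <- function(treated, mock, condition = "treated",
                               direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  treated <- as.numeric(treated); mock <- as.numeric(mock)
  if (length(treated) < 2L || length(mock) < 2L) {
    stop("each arm needs n >= 2", call. = FALSE)
  }
  if (mean(mock) == 0) stop("mock arm mean is zero", call. = FALSE)
  fold <- mean(treated) / mean(mock)
  tt <- auto_t_test(treated, mock, tails = 1,
                    direction = if (direction == "increase") "greater"
                                else "less")
  right_way <- if (direction == "increase") fold > 1 else fold < 1
  structure(list(condition = condition, direction = direction,
                 fold_change = fold, p_value = tt$p_value, stars = tt$stars,
                 responder = right_way && tt$p_value < 0.05,
                 test = tt$test),
            class = "treatment_response")
}

#' @export
print.treatment_response <- function(x, ...) {
  cat(sprintf("<%s> fold %.3g, one-tailed p = %.4g %s -> %s\n",
              x$condition, x$fold_change, x$p_value, x$stars,
              if (x$responder) "responder" else "non-responder"))
  invisible(x)
}

#' ApoA1-stabilization call on surface expression
#'
#' The cholesterol acceptor stabilizes the transporter at the cell surface;
#' a significant one-tailed *increase* of surface expression after acceptor
#' treatment vs mock indicates the variant retains acceptor interaction.
#'
#' @param apoa1_surface,mock_surface per-experiment surface expressions
#'   (% of WT), n >= 2 each.
#' @return a `treatment_response` with `condition = "apoa1"`; its
#'   `responder` flag reads "retains ApoA1 interaction".
#' @export
stabilization_call <- function(apoa1_surface, mock_surface) {
  treatment_response(apoa1_surface, mock_surface, condition = "apoa1",
                     direction = "increase")
}
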