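# Efflux arithmetic: well signals -> corrected, WT-normalized activities.
#
# The fixed composition order is:
#   fraction -> leakage correction -> mock subtraction -> (optional renilla
#   rescaling) -> WT normalization,
# all per experiment. Corrections operate on efflux *fractions*, not raw
# signals, because mock and variant wells carry different cell loads.

#' Cholesterol-efflux fraction of a well
#'
#' `medium / (medium + lysate)`: the fraction of labelled cholesterol found in
#' the acceptor medium after the efflux incubation. Invariant to common
#' rescaling of both signals.
#'
#' @param medium,lysate non-negative fluorescence reads (RFU); vectorized.
#' @return efflux fraction(s) in \[0, 1\].
#' @examples
#' compute_efflux_fraction(300, 700)  # 0.3
#' @export
compute_efflux_fraction <- function(medium, lysate) {
  if (any(medium < 0, na.rm = TRUE) || any(lysate < 0, na.rm = TRUE)) {
    stop("signals must be >= 0", call. = FALSE)
  }
  tot <- medium + lysate
  if (any(tot <= 0, na.rm = TRUE)) {
    stop("degenerate well: medium + lysate must be > 0", call. = FALSE)
  }
  medium / tot
}

#' Correct an efflux fraction for acceptor-independent leakage
#'
#' Subtracts the fraction measured in mock-transfected wells *without*
#' acceptor (passive label leakage). Negative results are legitimate noise
#' excursions and are passed through, not clamped.
#'
#' @param fraction efflux fraction(s) in \[0, 1\].
#' @param leakage_fraction leakage fraction from mock/no-acceptor wells.
#' @return leakage-corrected fraction(s); may be negative.
#' @export
correct_leakage <- function(fraction, leakage_fraction) {
  stopifnot(all(fraction >= 0 & fraction <= 1, na.rm = TRUE),
            all(leakage_fraction >= 0 & leakage_fraction <= 1, na.rm = TRUE))
  fraction - leakage_fraction
}

#' ABCA1-specific efflux
#'
#' Subtracts the (leakage-corrected) efflux of mock-transfected cells with
#' acceptor — the ABCA1-unspecific efflux — from a construct's
#' leakage-corrected fraction. Both must come from the same experiment.
#'
#' @param construct_fraction,mock_fraction leakage-corrected fractions.
#' @return specific efflux; may be negative (flagged downstream, not clamped).
#' @export
compute_specific_efflux <- function(construct_fraction, mock_fraction) {
  if (length(mock_fraction) == 0L || anyNA(mock_fraction)) {
    stop("pairing error: no mock well available for this experiment",
         call. = FALSE)
  }
  construct_fraction - mock_fraction
}

#' Rescale specific efflux to a common transfection efficiency
#'
#' Optional (off by default in the pipeline): the co-transfected renilla
#' luciferase signal reports per-well transfection efficiency;
#' `specific * wt_renilla / renilla` puts every construct on the wild-type
#' efficiency scale.
#'
#' @param specific specific efflux fraction(s).
#' @param renilla,wt_renilla positive luminescence reads (LU).
#' @return rescaled specific efflux.
#' @export
renilla_adjust <- function(specific, renilla, wt_renilla) {
  if (any(!is.finite(renilla)) || any(renilla <= 0) ||
      any(!is.finite(wt_renilla)) || any(wt_renilla <= 0)) {
    stop("renilla luminescence must be positive", call. = FALSE)
  }
  specific * (wt_renilla / renilla)
}

#' Normalize specific efflux to the wild type of the same experiment
#'
#' @param specific specific efflux fraction(s).
#' @param wt_specific wild-type specific efflux of the *same* experiment;
#'   must be positive or the experiment is invalid.
#' @return percent of WT; negative inputs yield negative percent here (the
#'   pipeline clamps the *reported* value at 0 and keeps the raw one).
#' @export
normalize_to_wt <- function(specific, wt_specific) {
  if (length(wt_specific) != 1L || !is.finite(wt_specific) ||
      wt_specific <= 0) {
    stop("experiment invalid: wild-type specific efflux must be > 0",
         call. = FALSE)
  }
  # ratio first: keeps the WT self-ratio exactly 1, hence WT exactly 100%
  100 * (specific / wt_specific)
}

#' Process a well table into per-construct, per-experiment activities
#'
#' Applies the fixed correction order within each experiment: well fractions,
#' leakage correction using that experiment's mock/no-acceptor wells, mock
#' subtraction using its mock/acceptor wells, optional renilla rescaling, and
#' normalization to that experiment's WT. Replicate wells of a construct are
#' averaged on the specific-efflux scale before normalization.
#'
#' @param wells a `well_table` data.frame (columns `construct`, `condition`,
#'   `medium`, `lysate`, `renilla`, `experiment`; `replicate` optional).
#' @param renilla_normalize logical; apply [renilla_adjust()] (default FALSE —
#'   renilla is treated as a transfection-efficiency monitor, not an applied
#'   correction).
#' @return an `efflux_result` data.frame: one row per construct x experiment
#'   with `raw_fraction`, `leakage_corrected_fraction`, `specific_efflux`,
#'   `relative_activity` (clamped at 0), `relative_activity_raw`,
#'   `n_replicates`. Mock wells are consumed by the corrections and do not
#'   appear as rows.
#' @examples
#' cfg <- sim_config(seed = 1, constructs = data.frame(name = "v1",
#'   activity = 50), noise_cv = 0, load_cv = 0, renilla_cv = 0)
#' process_efflux(simulate_plate(cfg))
#' @export
process_efflux <- function(wells, renilla_normalize = FALSE) {
  wells <- as.data.frame(wells)
  need <- c("construct", "condition", "medium", "lysate", "experiment")
  if (!all(need %in% names(wells))) {
    stop("well table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  res <- lapply(split(wells, wells$experiment), function(w) {
    exp_id <- w$experiment[1]
    frac <- compute_efflux_fraction(w$medium, w$lysate)
    leak_rows <- w$construct == "MOCK" & w$condition == "no_acceptor"
    if (!any(leak_rows)) {
      stop("missing mock/no-acceptor well in experiment ", exp_id,
           call. = FALSE)
    }
    leak <- mean(frac[leak_rows])
    lc <- correct_leakage(frac, leak)
    mock_rows <- w$construct == "MOCK" & w$condition == "with_acceptor"
    if (!any(mock_rows)) {
      stop("pairing error: missing mock/acceptor well in experiment ", exp_id,
           call. = FALSE)
    }
    mock_lc <- mean(lc[mock_rows])
    keep <- w$construct != "MOCK" & w$condition == "with_acceptor"
    spec <- compute_specific_efflux(lc[keep], mock_lc)
    if (renilla_normalize) {
      ren <- w$renilla[keep]
      wt_ren <- mean(w$renilla[keep][w$construct[keep] == "WT"])
      spec <- renilla_adjust(spec, ren, wt_ren)
    }
    cons <- w$construct[keep]
    agg <- function(v) as.numeric(tapply(v, cons, mean))
    nms <- sort(unique(cons))
    spec_m <- as.numeric(tapply(spec, cons, mean))
    if (!"WT" %in% nms) {
      stop("missing WT wells in experiment ", exp_id, call. = FALSE)
    }
    wt_spec <- spec_m[match("WT", nms)]
    rel_raw <- normalize_to_wt(spec_m, wt_spec)
    data.frame(construct = nms, experiment = exp_id,
               raw_fraction = agg(frac[keep]),
               leakage_corrected_fraction = agg(lc[keep]),
               specific_efflux = spec_m,
               relative_activity = pmax(rel_raw, 0),
               relative_activity_raw = rel_raw,
               n_replicates = as.integer(table(cons)[nms]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  row.names(out) <- NULL
  class(out) <- c("efflux_result", "data.frame")
  out
}

#' Summarize activities across experiments
#'
#' Mean, sample SD and n of per-experiment relative activities for each
#' construct, plus a two-sample comparison vs the WT per-experiment values
#' (which are identically 100 by construction, so WT rows report no test).
#'
#' @param efflux an `efflux_result` from [process_efflux()].
#' @param vs_wt logical; add p-values/stars from [auto_t_test()] against the
#'   WT per-experiment activities (two-tailed).
#' @return data.frame with one row per construct: `mean_activity`, `sd`, `n`,
#'   and if `vs_wt` also `p_value` and `stars`.
#' @export
summarize_activity <- function(efflux, vs_wt = TRUE) {
  efflux <- as.data.frame(efflux)
  sp <- split(efflux$relative_activity, efflux$construct)
  wt <- sp[["WT"]]
  rows <- lapply(names(sp), function(nm) {
    s <- aggregate_replicates(sp[[nm]])
    out <- data.frame(construct = nm, mean_activity = s$mean, sd = s$sd,
                      n = s$n, stringsAsFactors = FALSE)
    if (vs_wt) {
      if (nm == "WT" || is.null(wt) || stats::var(sp[[nm]]) + stats::var(wt) == 0) {
        out$p_value <- NA_real_
        out$stars <- ""
      } else {
        tt <- auto_t_test(sp[[nm]], wt, tails = 2)
        out$p_value <- tt$p_value
        out$stars <- tt$stars
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
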