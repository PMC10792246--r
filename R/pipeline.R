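# Orchestration: simulate -> efflux -> calibrate -> classify -> quant ->
# coloc -> report, seed-reproducible, with a JSON provenance record.

#' Load a fixture directory written by [make_fixtures()]
#'
#' @param dir fixture directory.
#' @return the same list shape [make_fixtures()] returns in memory.
#' @export
load_fixtures <- function(dir) {
  need <- file.path(dir, c("variants.tsv", "wells.tsv", "msa.fasta"))
  if (!all(file.exists(need))) {
    stop("not a fixture directory: ", dir, call. = FALSE)
  }
  arms <- c("mock_treated", "epoxomicin", "pba_4")
  treat <- lapply(stats::setNames(arms, arms), function(arm) {
    p <- file.path(dir, paste0("wells_", arm, ".tsv"))
    if (file.exists(p)) read_well_table(p) else NULL
  })
  manifest <- NULL; images <- NULL
  if (file.exists(file.path(dir, "images.tsv"))) {
    manifest <- read_tsv(file.path(dir, "images.tsv"))
    images <- lapply(seq_len(nrow(manifest)), function(i) {
      image_pair(read_image_matrix(file.path(dir, manifest$file_a[i])),
                 read_image_matrix(file.path(dir, manifest$file_b[i])),
                 target_r = manifest$target_r[i])
    })
  }
  truth <- NULL
  if (file.exists(file.path(dir, "truth.json"))) {
    truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
  }
  list(
    variants = read_variant_table(file.path(dir, "variants.tsv")),
    wells = read_well_table(file.path(dir, "wells.tsv")),
    treat = treat,
    blots = if (file.exists(file.path(dir, "blots.tsv"))) {
      read_blot_table(file.path(dir, "blots.tsv"))
    },
    surface = if (file.exists(file.path(dir, "surface.tsv"))) {
      read_surface_table(file.path(dir, "surface.tsv"))
    },
    msa = read_msa(file.path(dir, "msa.fasta")),
    images = images, image_manifest = manifest, truth = truth
  )
}

# specific efflux of treated-arm constructs normalized to the mock-treated
# WT of the same experiment (arms stay comparable to their mock baseline)
.relative_to_mock_wt <- function(arm_wells, mock_wells,
                                 renilla_normalize = FALSE) {
  arm <- process_efflux(arm_wells, renilla_normalize)
  mock <- process_efflux(mock_wells, renilla_normalize)
  wt_spec <- stats::setNames(
    mock$specific_efflux[mock$construct == "WT"],
    mock$experiment[mock$construct == "WT"])
  if (any(wt_spec <= 0)) {
    stop("experiment invalid: mock-treated WT specific efflux <= 0",
         call. = FALSE)
  }
  arm$relative_activity <- pmax(
    0, 100 * arm$specific_efflux / wt_spec[as.character(arm$experiment)])
  arm[c("construct", "experiment", "relative_activity")]
}

#' Run the full variant-characterization pipeline
#'
#' Stages: per-experiment efflux correction and WT normalization;
#' across-experiment summaries with two-tailed tests vs WT; conservation
#' counting of every query variant in the alignment; threshold derivation
#' (pathogenic = best-performing pathogenic control, benevolent = rounded
#' mean of the three weakest conservation-supported variants); three-class
#' calls and domain annotation; densitometry totals; surface expression;
#' one-tailed rescue (epoxomicin, 4-PBA) and ApoA1-stabilization calls vs the
#' mock-treated arm; Pearson colocalization summaries. Deterministic given
#' the fixture; writes all tables plus a JSON provenance record when
#' `out_dir` is given.
#'
#' @param fixtures a [make_fixtures()] list or a fixture directory path;
#'   `NULL` simulates a fresh default fixture from `seed`.
#' @param out_dir optional output directory.
#' @param seed seed used only when `fixtures` is `NULL`.
#' @param renilla_normalize apply the renilla transfection-efficiency
#'   rescaling (off by default).
#' @param benevolent_boundary `"ge"` (default) or `"gt"`; see
#'   [threshold_set()].
#' @param thresholds optional [threshold_set()] overriding derivation.
#' @param log emit stage messages to stderr.
#' @return a `variant_report` list: `report` (one row per variant),
#'   `thresholds`, `activity`, `efflux`, `rescue`, `stabilization`, `coloc`,
#'   `provenance`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(seed = 7)
#' head(rep$report)
#' }
#' @export
run_pipeline <- function(fixtures = NULL, out_dir = NULL, seed = 1L,
                         renilla_normalize = FALSE,
                         benevolent_boundary = c("ge", "gt"),
                         thresholds = NULL, log = FALSE) {
  benevolent_boundary <- match.arg(benevolent_boundary)
  say <- function(...) if (log) message("[abca1flux] ", ...)
  if (is.null(fixtures)) {
    say("simulating default fixture, seed ", seed)
    fixtures <- make_fixtures(seed = seed)
  } else if (is.character(fixtures)) {
    say("loading fixtures from ", fixtures)
    fixtures <- load_fixtures(fixtures)
  }
  variants <- fixtures$variants
  pv <- parse_hgvs_p(variants$hgvs_p)
  variants$position <- pv$position

  say("efflux stage")
  efflux <- process_efflux(fixtures$wells, renilla_normalize)
  activity <- summarize_activity(efflux, vs_wt = TRUE)
  act_of <- function(nm) {
    activity$mean_activity[match(nm, activity$construct)]
  }

  say("calibration stage")
  is_query <- variants$role == "query"
  cons_n <- vapply(variants$hgvs_p, function(v) {
    species_with_alt_as_reference(fixtures$msa, v)
  }, numeric(1))
  eligible <- is_query & calibration_eligible(cons_n)
  if (is.null(thresholds)) {
    path_ctrl <- variants$hgvs_p[variants$role == "pathogenic_control"]
    if (length(path_ctrl) == 0L) {
      stop("calibration error: fixture has no pathogenic controls",
           call. = FALSE)
    }
    ctrl_act <- stats::setNames(act_of(path_ctrl), path_ctrl)
    calib <- data.frame(hgvs_p = variants$hgvs_p[eligible],
                        mean_activity = act_of(variants$hgvs_p[eligible]),
                        stringsAsFactors = FALSE)
    thresholds <- threshold_set(
      pathogenic_cutoff = derive_pathogenic_threshold(ctrl_act),
      benevolent_cutoff = derive_benevolent_threshold(calib$mean_activity),
      calibration_variants = calib,
      control_anchor = names(ctrl_act)[which.max(ctrl_act)],
      benevolent_boundary = benevolent_boundary)
  }
  say(sprintf("thresholds: LOF < %g%%, benevolent %s %g%%",
              thresholds$pathogenic_cutoff,
              if (thresholds$benevolent_boundary == "ge") ">=" else ">",
              thresholds$benevolent_cutoff))

  say("classification stage")
  mean_act <- act_of(variants$hgvs_p)
  cls <- classify_activity(mean_act, thresholds)
  doms <- vapply(variants$position, function(p) {
    paste(annotate_domains(p), collapse = ",")
  }, character(1))

  say("protein quantification stage")
  totals <- surf <- NULL
  if (!is.null(fixtures$blots)) {
    q <- quantify_blots(fixtures$blots)
    q <- q[q$condition == "mock_treated", ]
    totals <- stats::setNames(
      as.numeric(tapply(q$total_pct_wt, q$construct, mean)),
      sort(unique(q$construct)))
  }
  if (!is.null(fixtures$surface)) {
    s <- quantify_surface(fixtures$surface)
    sm <- s[s$condition == "mock_treated", ]
    surf <- stats::setNames(
      as.numeric(tapply(sm$surface_pct_wt, sm$construct, mean)),
      sort(unique(sm$construct)))
  }

  say("treatment-response stage")
  rescue <- list()
  if (!is.null(fixtures$treat$mock_treated)) {
    mock_rel <- .relative_to_mock_wt(fixtures$treat$mock_treated,
                                     fixtures$treat$mock_treated,
                                     renilla_normalize)
    for (arm in intersect(c("epoxomicin", "pba_4"),
                          names(fixtures$treat))) {
      if (is.null(fixtures$treat[[arm]])) next
      arm_rel <- .relative_to_mock_wt(fixtures$treat[[arm]],
                                      fixtures$treat$mock_treated,
                                      renilla_normalize)
      sp_a <- split(arm_rel$relative_activity, arm_rel$construct)
      sp_m <- split(mock_rel$relative_activity, mock_rel$construct)
      rescue[[arm]] <- do.call(rbind, lapply(names(sp_a), function(nm) {
        tr <- treatment_response(sp_a[[nm]], sp_m[[nm]], condition = arm,
                                 direction = "increase")
        data.frame(construct = nm, condition = arm,
                   fold_change = tr$fold_change, p_value = tr$p_value,
                   stars = tr$stars, responder = tr$responder,
                   stringsAsFactors = FALSE)
      }))
    }
  }
  rescue_df <- if (length(rescue)) do.call(rbind, rescue) else NULL
  if (!is.null(rescue_df)) row.names(rescue_df) <- NULL

  stab_df <- NULL
  if (!is.null(fixtures$surface) &&
      "apoa1" %in% fixtures$surface$condition) {
    s <- quantify_surface(fixtures$surface)
    sp <- split(s, s$construct)
    stab_df <- do.call(rbind, lapply(names(sp), function(nm) {
      x <- sp[[nm]]
      ap <- x$surface_pct_wt[x$condition == "apoa1"]
      mo <- x$surface_pct_wt[x$condition == "mock_treated"]
      if (length(ap) < 2L || length(mo) < 2L) return(NULL)
      tr <- stabilization_call(ap, mo)
      data.frame(construct = nm, fold_change = tr$fold_change,
                 p_value = tr$p_value, stars = tr$stars,
                 stabilized = tr$responder, stringsAsFactors = FALSE)
    }))
    if (!is.null(stab_df)) row.names(stab_df) <- NULL
  }

  say("colocalization stage")
  coloc_df <- NULL
  if (!is.null(fixtures$images)) {
    man <- fixtures$image_manifest
    man$r <- vapply(fixtures$images,
                    function(p) pearson_coloc(p)$r, numeric(1))
    sp <- split(man, man$construct)
    coloc_df <- do.call(rbind, lapply(names(sp), function(nm) {
      s <- summarize_coloc(sp[[nm]]$r, sp[[nm]]$experiment)
      data.frame(construct = nm, r = s$mean, sd = s$sd,
                 n_experiments = s$n, stringsAsFactors = FALSE)
    }))
    row.names(coloc_df) <- NULL
  }

  say("report stage")
  pick <- function(tab, nm, col) {
    if (is.null(tab)) return(rep(NA, length(nm)))
    tab[[col]][match(nm, tab$construct)]
  }
  named_pick <- function(v, nm) if (is.null(v)) rep(NA_real_, length(nm)) else unname(v[nm])
  resc <- function(arm, col) {
    if (is.null(rescue_df)) return(rep(NA, length(variants$hgvs_p)))
    sub <- rescue_df[rescue_df$condition == arm, ]
    sub[[col]][match(variants$hgvs_p, sub$construct)]
  }
  report <- data.frame(
    hgvs_p = variants$hgvs_p,
    role = variants$role,
    source = if ("source" %in% names(variants)) variants$source else NA,
    mean_activity = mean_act,
    sd_activity = activity$sd[match(variants$hgvs_p, activity$construct)],
    n = activity$n[match(variants$hgvs_p, activity$construct)],
    p_vs_wt = activity$p_value[match(variants$hgvs_p, activity$construct)],
    stars = activity$stars[match(variants$hgvs_p, activity$construct)],
    conservation_n = as.integer(cons_n),
    calibration_variant = eligible,
    class = as.character(cls),
    domains = doms,
    total_pct_wt = named_pick(totals, variants$hgvs_p),
    surface_pct_wt = named_pick(surf, variants$hgvs_p),
    epoxomicin_fold = resc("epoxomicin", "fold_change"),
    epoxomicin_p = resc("epoxomicin", "p_value"),
    epoxomicin_responder = resc("epoxomicin", "responder"),
    pba_fold = resc("pba_4", "fold_change"),
    pba_p = resc("pba_4", "p_value"),
    pba_responder = resc("pba_4", "responder"),
    apoa1_fold = pick(stab_df, variants$hgvs_p, "fold_change"),
    apoa1_p = pick(stab_df, variants$hgvs_p, "p_value"),
    apoa1_stabilized = pick(stab_df, variants$hgvs_p, "stabilized"),
    coloc_r = pick(coloc_df, variants$hgvs_p, "r"),
    coloc_sd = pick(coloc_df, variants$hgvs_p, "sd"),
    stringsAsFactors = FALSE
  )
  provenance <- list(
    package = "abca1flux",
    version = as.character(utils::packageVersion("abca1flux")),
    seed = fixtures$seed %||% seed,
    renilla_normalize = renilla_normalize,
    benevolent_boundary = thresholds$benevolent_boundary,
    pathogenic_cutoff = thresholds$pathogenic_cutoff,
    benevolent_cutoff = thresholds$benevolent_cutoff,
    control_anchor = thresholds$control_anchor,
    calibration_variants = thresholds$calibration_variants,
    note = paste("benevolent boundary: the source text's main rule (>=) is",
                 "used; its figure legend states (>) — they differ only",
                 "exactly at the cutoff")
  )
  out <- structure(list(report = report, thresholds = thresholds,
                        activity = activity, efflux = efflux,
                        rescue = rescue_df, stabilization = stab_df,
                        coloc = coloc_df, provenance = provenance),
                   class = "variant_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fmt <- function(d) {
      d[] <- lapply(d, function(col) {
        if (is.numeric(col)) signif(col, 10) else col
      })
      d
    }
    write_tsv(fmt(report), file.path(out_dir, "report.tsv"))
    write_tsv(fmt(as.data.frame(efflux)), file.path(out_dir, "efflux.tsv"))
    write_tsv(fmt(activity), file.path(out_dir, "activity.tsv"))
    if (!is.null(rescue_df)) {
      write_tsv(fmt(rescue_df), file.path(out_dir, "rescue.tsv"))
    }
    if (!is.null(stab_df)) {
      write_tsv(fmt(stab_df), file.path(out_dir, "stabilization.tsv"))
    }
    if (!is.null(coloc_df)) {
      write_tsv(fmt(coloc_df), file.path(out_dir, "coloc.tsv"))
    }
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  out
}

#' @export
print.variant_report <- function(x, ...) {
  n <- table(x$report$class[x$report$role == "query"])
  cat("<variant_report>", sum(x$report$role == "query"), "query variants:",
      paste(names(n), n, sep = "=", collapse = ", "), "\n")
  print(x$thresholds)
  invisible(x)
}
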