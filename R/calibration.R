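# Conservation-calibrated thresholds and three-class functional calls.
#
# The pathogenic cutoff anchors on the best-performing characterized
# disease-causing control; the benevolent cutoff is the rounded mean of the
# three weakest "calibration" variants, i.e. variants whose alternate residue
# is the reference in more than two species of a vertebrate alignment (such
# residues demonstrably support a functional transporter).

.aa1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Parse HGVS p. missense notation (one-letter codes)
#'
#' Accepts `p.E284K` or `E284K`. Three-letter codes, nonsense (`X`/`*`),
#' frameshift and any non-missense notation are explicitly unsupported and
#' raise a parse error.
#'
#' @param text character vector of variant strings.
#' @return data.frame with columns `hgvs_p` (normalized, with `p.` prefix),
#'   `ref_aa`, `position`, `alt_aa`.
#' @examples
#' parse_hgvs_p(c("p.E284K", "K939M"))
#' @export
parse_hgvs_p <- function(text) {
  text <- as.character(text)
  m <- regmatches(text, regexec("^(?:p\\.)?([A-Za-z*])(\\d+)([A-Za-z*])$",
                                text))
  rows <- lapply(seq_along(text), function(i) {
    g <- m[[i]]
    if (length(g) != 4L) {
      stop("parse error: '", text[i],
           "' is not one-letter missense p. notation", call. = FALSE)
    }
    ref <- g[2]; alt <- g[4]
    if (!(ref %in% .aa1) || !(alt %in% .aa1)) {
      stop("parse error: '", text[i],
           "' uses residues outside the 20 standard amino acids ",
           "(nonsense/frameshift notation is unsupported)", call. = FALSE)
    }
    if (ref == alt) {
      stop("parse error: '", text[i], "' is synonymous", call. = FALSE)
    }
    pos <- as.integer(g[3])
    if (pos < 1L) stop("parse error: position must be >= 1", call. = FALSE)
    data.frame(hgvs_p = paste0("p.", ref, pos, alt), ref_aa = ref,
               position = pos, alt_aa = alt, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Count species carrying a variant's alternate residue as their reference
#'
#' Maps the variant's residue position into the alignment through the
#' ungapped human row (gaps in the human row are skipped), then counts
#' non-human rows whose residue at that column equals the alternate amino
#' acid. Gapped rows count as non-matching.
#'
#' @param msa an `msa` object ([simulate_msa()], [read_msa()]): named
#'   character vector of equal-length aligned sequences with attribute
#'   `human_id`.
#' @param variant HGVS p. string or one row of [parse_hgvs_p()] output.
#' @param human_id identifier of the human reference row; defaults to the
#'   object's `human_id` attribute.
#' @return integer count.
#' @export
species_with_alt_as_reference <- function(msa, variant,
                                          human_id = attr(msa, "human_id")) {
  if (is.character(variant)) variant <- parse_hgvs_p(variant)
  if (is.null(human_id) || !human_id %in% names(msa)) {
    stop("mapping error: human reference row not found in alignment",
         call. = FALSE)
  }
  human <- strsplit(unname(msa[[human_id]]), "")[[1]]
  non_gap <- which(human != "-")
  if (variant$position > length(non_gap)) {
    stop("mapping error: position ", variant$position,
         " beyond the ungapped human sequence", call. = FALSE)
  }
  col <- non_gap[variant$position]
  others <- msa[setdiff(names(msa), human_id)]
  sum(vapply(others, function(s) substr(s, col, col), character(1)) ==
        variant$alt_aa)
}

#' Is a variant eligible as a calibration variant?
#'
#' Eligible when its alternate residue appears as the reference in *more
#' than* `min_exceed` species (strict inequality; the default reproduces the
#' "more than two of the species" rule).
#'
#' @param count species count from [species_with_alt_as_reference()];
#'   vectorized.
#' @param min_exceed threshold the count must exceed (default 2).
#' @return logical.
#' @export
calibration_eligible <- function(count, min_exceed = 2L) {
  if (any(count < 0)) stop("counts must be >= 0", call. = FALSE)
  count > min_exceed
}

#' Derive the benevolent activity cutoff
#'
#' Mean of the `k` lowest calibration-variant activities, rounded to the
#' nearest integer percent. With the published calibration activities
#' (79, 80, 82) this yields the 80% cutoff.
#'
#' @param calibration_activities mean activities (% of WT) of the eligible
#'   calibration variants.
#' @param k number of lowest activities to average (default 3).
#' @return integer percent.
#' @examples
#' derive_benevolent_threshold(c(79, 80, 82, 95, 101, 88, 110, 97, 85, 93))
#' @export
derive_benevolent_threshold <- function(calibration_activities, k = 3L) {
  v <- as.numeric(calibration_activities)
  if (length(v) < k) {
    stop("calibration error: need at least ", k,
         " eligible calibration variants", call. = FALSE)
  }
  round(mean(sort(v)[seq_len(k)]))
}

#' Derive the pathogenic activity cutoff
#'
#' The cutoff is anchored on the characterized disease-causing control with
#' the *highest* residual activity: anything below that has no precedent of
#' being tolerated.
#'
#' @param control_activities mean activities (% of WT) of pathogenic
#'   controls; optionally named by variant.
#' @return numeric percent (the maximum control activity).
#' @export
derive_pathogenic_threshold <- function(control_activities) {
  v <- as.numeric(control_activities)
  if (length(v) == 0L) {
    stop("calibration error: no pathogenic controls supplied", call. = FALSE)
  }
  max(v)
}

#' Bundle classification thresholds
#'
#' @param pathogenic_cutoff,benevolent_cutoff percents with
#'   `0 < pathogenic < benevolent <= 100`.
#' @param calibration_variants optional data.frame (variant, mean activity)
#'   recording how the benevolent cutoff was derived.
#' @param control_anchor optional name of the control anchoring the
#'   pathogenic cutoff.
#' @param benevolent_boundary `"ge"` (activity >= cutoff is benevolent; the
#'   main-text rule, default) or `"gt"` (the figure-legend variant; the two
#'   disagree only exactly at the cutoff).
#' @return a `threshold_set`.
#' @export
threshold_set <- function(pathogenic_cutoff, benevolent_cutoff,
                          calibration_variants = NULL, control_anchor = NULL,
                          benevolent_boundary = c("ge", "gt")) {
  if (!(pathogenic_cutoff > 0 && pathogenic_cutoff < benevolent_cutoff &&
        benevolent_cutoff <= 100)) {
    stop("need 0 < pathogenic_cutoff < benevolent_cutoff <= 100",
         call. = FALSE)
  }
  structure(list(pathogenic_cutoff = as.numeric(pathogenic_cutoff),
                 benevolent_cutoff = as.numeric(benevolent_cutoff),
                 calibration_variants = calibration_variants,
                 control_anchor = control_anchor,
                 benevolent_boundary = match.arg(benevolent_boundary)),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  op <- if (x$benevolent_boundary == "ge") ">=" else ">"
  cat(sprintf("<threshold_set> loss-of-function < %g%%, benevolent %s %g%%\n",
              x$pathogenic_cutoff, op, x$benevolent_cutoff))
  invisible(x)
}

#' Three-class functional call from mean activity
#'
#' `loss_of_function` below the pathogenic cutoff, `benevolent` at/above the
#' benevolent cutoff (boundary per the threshold set), `uncertain` in
#' between. The call uses the across-experiment mean only; SD is reported but
#' never gates the call.
#'
#' @param mean_activity percent(s) of WT; vectorized.
#' @param thresholds a [threshold_set()].
#' @return factor with levels `loss_of_function`, `uncertain`, `benevolent`.
#' @examples
#' classify_activity(c(49, 65, 80), threshold_set(50, 80))
#' @export
classify_activity <- function(mean_activity, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  x <- as.numeric(mean_activity)
  ben <- if (thresholds$benevolent_boundary == "ge") {
    x >= thresholds$benevolent_cutoff
  } else {
    x > thresholds$benevolent_cutoff
  }
  out <- ifelse(x < thresholds$pathogenic_cutoff, "loss_of_function",
                ifelse(ben, "benevolent", "uncertain"))
  factor(out, levels = c("loss_of_function", "uncertain", "benevolent"))
}

#' Residue-interval map of ABCA1 functional subdomains
#'
#' Gateway and annulus residue sets follow the published phospholipid-
#' translocation model of the transporter (gateway 564-592; annulus 69,
#' 71-80, 363, 368-379; central annulus 73, 74, 77, 371, 375). ECD1/ECD2
#' extents are approximate, taken from the structural literature, and serve
#' annotation only.
#'
#' @return named list of integer residue sets.
#' @export
domain_map <- function() {
  list(
    ECD1 = 44:639,
    ECD2 = 1366:1657,
    gateway = 564:592,
    annulus = c(69L, 71:80, 363L, 368:379),
    annulus_central = c(73L, 74L, 77L, 371L, 375L)
  )
}

#' Domain labels containing a variant's position
#'
#' @param variant HGVS p. string, a row of [parse_hgvs_p()] output, or a bare
#'   residue position.
#' @param map named list of residue sets (default [domain_map()]).
#' @return character vector of matching labels (possibly empty).
#' @examples
#' annotate_domains("p.R579Q")   # gateway (and ECD1)
#' @export
annotate_domains <- function(variant, map = domain_map()) {
  pos <- if (is.numeric(variant)) {
    as.integer(variant)
  } else {
    if (is.character(variant)) variant <- parse_hgvs_p(variant)
    variant$position
  }
  names(map)[vapply(map, function(set) pos %in% set, logical(1))]
}
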