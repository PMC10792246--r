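# Synthetic-data generators. Every stage of the pipeline can be exercised on
# simulated inputs whose ground truth is known, because the study's raw
# well-level data are not publicly deposited.

.load_scale <- 1000     # RFU scale of total per-well label
.renilla_scale <- 1e4   # LU scale of the renilla transfection reporter
.actin_scale <- 1000    # densitometry scale of a beta-actin band
.surface_scale <- 500   # densitometry scale of a WT streptavidin pull-down band

#' Simulate a plate of cholesterol-efflux wells
#'
#' For every experiment and construct one (or `wells_per_construct`) wells are
#' drawn. A well's total label `T` is lognormal around the load scale with CV
#' `load_cv`. Each construct x experiment has a transfection-efficiency factor
#' `f` (lognormal, unit mean, CV `renilla_cv`) reported through the renilla
#' channel. The medium fraction of an acceptor well is
#' `f * wt_true_specific_efflux * activity/100 + mock_unspecific_efflux +
#' leakage_fraction`; mock wells carry no ABCA1-specific term, and wells
#' without acceptor retain only the leakage term. Medium and lysate reads get
#' independent multiplicative noise with CV `noise_cv`. Mock wells with and
#' without acceptor are included in every experiment.
#'
#' @param config a [sim_config()].
#' @param condition optional treatment-arm name; the construct's
#'   activity-fold from `config$treatment_effects` is applied.
#' @return a `well_table` data.frame with columns `construct`, `condition`
#'   (`with_acceptor`/`no_acceptor`), `medium`, `lysate`, `renilla`,
#'   `experiment`, `replicate`, `treatment`.
#' @examples
#' wells <- simulate_plate(sim_config(seed = 1, constructs =
#'   data.frame(name = "p.E284K", activity = 20)))
#' @export
simulate_plate <- function(config, condition = "mock_treated") {
  stopifnot(inherits(config, "sim_config"))
  act <- c(WT = 100,
           stats::setNames(config$constructs$activity, config$constructs$name))
  if (!is.null(condition) && condition != "mock_treated") {
    for (nm in names(act)) {
      act[nm] <- act[nm] * treatment_fold(config, condition, nm, "activity")
    }
  }
  nms <- names(act)
  E <- config$n_experiments
  W <- config$wells_per_construct
  with_seed(stage_seed(config$seed, "plate") +
              match(condition, c("mock_treated", "epoxomicin", "pba_4",
                                 "apoa1"), nomatch = 9L), {
    # transfection factor per construct x experiment (one transfection feeds
    # all replicate wells of that construct in that experiment)
    f <- matrix(rlnorm_unit(length(nms) * E, config$renilla_cv),
                nrow = length(nms), dimnames = list(nms, NULL))
    grid <- expand.grid(replicate = seq_len(W), construct = nms,
                        experiment = seq_len(E), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    mock <- expand.grid(replicate = seq_len(W),
                        construct = "MOCK",
                        condition = c("with_acceptor", "no_acceptor"),
                        experiment = seq_len(E), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    grid$condition <- "with_acceptor"
    grid <- rbind(grid[c("construct", "condition", "experiment", "replicate")],
                  mock[c("construct", "condition", "experiment", "replicate")])
    n <- nrow(grid)
    is_mock <- grid$construct == "MOCK"
    has_acc <- grid$condition == "with_acceptor"
    fw <- ifelse(is_mock, NA_real_,
                 f[cbind(match(grid$construct, nms), grid$experiment)])
    e_spec <- ifelse(is_mock, 0,
                     fw * config$wt_true_specific_efflux *
                       act[grid$construct] / 100)
    frac <- ifelse(has_acc,
                   e_spec + config$mock_unspecific_efflux +
                     config$leakage_fraction,
                   config$leakage_fraction)
    if (any(frac >= 1)) {
      stop("bounds error: drawn efflux + leakage >= 1; ",
           "reduce activity, efflux or CV settings", call. = FALSE)
    }
    total <- .load_scale * rlnorm_unit(n, config$load_cv)
    medium <- total * frac * rlnorm_unit(n, config$noise_cv)
    lysate <- total * (1 - frac) * rlnorm_unit(n, config$noise_cv)
    renilla <- ifelse(is_mock, NA_real_,
                      .renilla_scale * fw * rlnorm_unit(n, config$noise_cv))
    out <- data.frame(construct = grid$construct, condition = grid$condition,
                      medium = medium, lysate = lysate, renilla = renilla,
                      experiment = grid$experiment,
                      replicate = grid$replicate,
                      treatment = condition %||% "mock_treated",
                      stringsAsFactors = FALSE)
    class(out) <- c("well_table", "data.frame")
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate western-blot densitometry lanes
#'
#' Each lane carries two ABCA1-specific bands (a doublet is typical for this
#' transporter) whose *sum*, normalized to the lane's beta-actin band, is
#' proportional to the construct's true total-protein level; the split between
#' the two bands carries no information. Lane load and reads get
#' multiplicative noise. A `MOCK` lane (zero ABCA1) is included per
#' experiment.
#'
#' @param config a [sim_config()].
#' @param conditions character vector of treatment arms to simulate; the
#'   per-construct `total`-fold from `config$treatment_effects` is applied.
#' @return a `blot_table` data.frame with columns `construct`, `band1`,
#'   `band2`, `actin`, `experiment`, `condition`.
#' @export
simulate_blots <- function(config, conditions = "mock_treated") {
  stopifnot(inherits(config, "sim_config"))
  nms <- c(names(config$protein_levels), "MOCK")
  E <- config$n_experiments
  with_seed(stage_seed(config$seed, "blots"), {
    grid <- expand.grid(construct = nms, experiment = seq_len(E),
                        condition = conditions, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    n <- nrow(grid)
    lvl <- ifelse(grid$construct == "MOCK", 0,
                  config$protein_levels[grid$construct])
    fold <- mapply(function(cond, cons) {
      if (cons == "MOCK") 1 else treatment_fold(config, cond, cons, "total")
    }, grid$condition, grid$construct)
    load <- rlnorm_unit(n, config$load_cv)
    actin <- .actin_scale * load * rlnorm_unit(n, config$noise_cv)
    bands <- .actin_scale * load * config$wt_band_actin_ratio * lvl * fold *
      rlnorm_unit(n, config$noise_cv)
    out <- data.frame(construct = grid$construct,
                      band1 = 0.6 * bands, band2 = 0.4 * bands,
                      actin = actin, experiment = grid$experiment,
                      condition = grid$condition, stringsAsFactors = FALSE)
    class(out) <- c("blot_table", "data.frame")
    out
  })
}

#' Simulate surface-biotinylation measurements
#'
#' One streptavidin pull-down band per construct, experiment and condition,
#' paired with that sample's measured total ABCA1 level (already normalized,
#' i.e. load-free). The per-construct `surface` and `total` folds from
#' `config$treatment_effects` act on the respective true levels.
#'
#' @inheritParams simulate_blots
#' @return a `surface_table` data.frame with columns `construct`,
#'   `surface_signal`, `total_level`, `experiment`, `condition`.
#' @export
simulate_surface <- function(config, conditions = "mock_treated") {
  stopifnot(inherits(config, "sim_config"))
  nms <- names(config$surface_levels)
  E <- config$n_experiments
  with_seed(stage_seed(config$seed, "surface"), {
    grid <- expand.grid(construct = nms, experiment = seq_len(E),
                        condition = conditions, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    n <- nrow(grid)
    sfold <- mapply(function(cond, cons) treatment_fold(config, cond, cons,
                                                        "surface"),
                    grid$condition, grid$construct)
    tfold <- mapply(function(cond, cons) treatment_fold(config, cond, cons,
                                                        "total"),
                    grid$condition, grid$construct)
    out <- data.frame(
      construct = grid$construct,
      surface_signal = .surface_scale * config$surface_levels[grid$construct] *
        sfold * rlnorm_unit(n, config$noise_cv),
      total_level = config$protein_levels[grid$construct] * tfold *
        rlnorm_unit(n, config$noise_cv),
      experiment = grid$experiment, condition = grid$condition,
      stringsAsFactors = FALSE)
    class(out) <- c("surface_table", "data.frame")
    out
  })
}

#' Simulate a vertebrate protein multiple sequence alignment
#'
#' Builds an alignment with one human reference row plus `n_species`
#' non-human rows. For each supplied variant, exactly `variant_support[[v]]`
#' non-human species carry the variant's alternate residue at the human-mapped
#' column; the human row carries the reference residue there. All other
#' columns diverge independently at rate `divergence`. Optional gap columns
#' (human row gapped) exercise position mapping through the ungapped human
#' sequence.
#'
#' @param n_species number of non-human species rows (default 29, the size of
#'   a typical vertebrate conservation panel for this protein).
#' @param variant_support named list/vector: HGVS p. variant -> number of
#'   non-human species carrying the alternate residue as their reference.
#' @param seed integer seed.
#' @param seq_length protein length; defaults to the largest variant position
#'   plus a margin (minimum 50).
#' @param divergence per-column substitution probability for non-human rows
#'   (variant columns excluded).
#' @param insert_gap_columns number of alignment columns in which the human
#'   row is gapped.
#' @param human_id FASTA identifier of the human row.
#' @return an `msa` object: named character vector of equal-length aligned
#'   sequences with a `human_id` attribute.
#' @examples
#' msa <- simulate_msa(29, variant_support = list(p.R130K = 3), seed = 1)
#' species_with_alt_as_reference(msa, "p.R130K")
#' @export
simulate_msa <- function(n_species = 29L, variant_support = list(),
                         seed = 1L, seq_length = NULL, divergence = 0.05,
                         insert_gap_columns = 0L,
                         human_id = "Homo_sapiens") {
  if (!is_count(n_species, 1L)) stop("n_species must be >= 1", call. = FALSE)
  support <- vapply(variant_support, as.numeric, numeric(1))
  if (any(support < 0) || any(support > n_species)) {
    stop("variant support counts must lie in [0, n_species]", call. = FALSE)
  }
  variants <- if (length(support)) parse_hgvs_p(names(support)) else NULL
  max_pos <- if (is.null(variants)) 0L else max(variants$position)
  if (is.null(seq_length)) seq_length <- max(50L, max_pos + 10L)
  if (max_pos > seq_length) {
    stop("variant position outside sequence length", call. = FALSE)
  }
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    human <- sample(aa, seq_length, replace = TRUE)
    if (!is.null(variants)) {
      # reference residues must agree when two variants share a position
      for (i in seq_len(nrow(variants))) {
        p <- variants$position[i]
        if (human[p] != variants$ref_aa[i]) {
          prev <- variants$position[seq_len(i - 1L)]
          if (p %in% prev) {
            stop("conflicting reference residues at position ", p,
                 call. = FALSE)
          }
          human[p] <- variants$ref_aa[i]
        }
      }
    }
    rows <- matrix(rep(human, each = n_species), nrow = n_species)
    var_cols <- if (is.null(variants)) integer() else unique(variants$position)
    mut_cols <- setdiff(seq_len(seq_length), var_cols)
    if (divergence > 0 && length(mut_cols)) {
      hits <- which(matrix(stats::runif(n_species * length(mut_cols)),
                           nrow = n_species) < divergence, arr.ind = TRUE)
      if (nrow(hits)) {
        cols <- mut_cols[hits[, 2]]
        repl <- vapply(cols, function(cl) sample(setdiff(aa, human[cl]), 1),
                       character(1))
        rows[cbind(hits[, 1], cols)] <- repl
      }
    }
    if (!is.null(variants)) {
      for (i in seq_len(nrow(variants))) {
        p <- variants$position[i]
        rows[, p] <- human[p]          # wipe stray divergence-era residues
        k <- support[i]
        if (k > 0) {
          rows[sample.int(n_species, k), p] <- variants$alt_aa[i]
        }
      }
    }
    seqs <- c(paste(human, collapse = ""),
              apply(rows, 1, paste, collapse = ""))
    names(seqs) <- c(human_id,
                     sprintf("species_%02d", seq_len(n_species)))
    if (insert_gap_columns > 0) {
      at <- sort(sample.int(seq_length, insert_gap_columns))
      chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
      for (j in rev(at)) {
        for (nm in names(chars)) {
          ins <- if (nm == human_id) "-" else sample(aa, 1)
          chars[[nm]] <- append(chars[[nm]], ins, after = j)
        }
      }
      seqs <- vapply(chars, paste, character(1), collapse = "")
    }
    structure(seqs, class = "msa", human_id = human_id)
  })
}

#' Simulate a two-channel microscopy image pair with known correlation
#'
#' Channels are built from a shared latent component plus independent noise so
#' that the *population* Pearson correlation equals `target_r`; the measured
#' sample correlation then fluctuates around `target_r` with the usual
#' `1/sqrt(n)` spread. With `exact = TRUE` the noise component is
#' Gram-Schmidt-orthogonalized against the shared component empirically, so
#' the *sample* correlation equals `target_r` to machine precision (useful for
#' exactness checks; keep `clip = FALSE` there, since clipping negatives
#' perturbs the correlation).
#'
#' @param target_r desired Pearson correlation in \[-1, 1\].
#' @param shape integer length-2 vector of image dimensions.
#' @param seed integer seed.
#' @param exact logical; make the sample correlation exactly `target_r`.
#' @param mean_intensity,sd_intensity affine intensity scaling (correlation is
#'   invariant to it).
#' @param clip clamp negative intensities to zero (default TRUE; intensities
#'   are non-negative by construction of real detectors).
#' @return an `image_pair`: list with matrices `channel_a`, `channel_b`,
#'   `mask = NULL` and the generative `target_r` as ground truth.
#' @examples
#' p <- simulate_image_pair(0.26, shape = c(64, 64), seed = 1)
#' pearson_coloc(p)$r
#' @export
simulate_image_pair <- function(target_r, shape = c(128L, 128L), seed = 1L,
                                exact = FALSE, mean_intensity = 500,
                                sd_intensity = 100, clip = TRUE) {
  if (!is.numeric(target_r) || length(target_r) != 1L || is.na(target_r) ||
      target_r < -1 || target_r > 1) {
    stop("target_r must lie in [-1, 1]", call. = FALSE)
  }
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L) || prod(shape) < 2L) {
    stop("degenerate shape: need at least 2 pixels", call. = FALSE)
  }
  n <- prod(shape)
  with_seed(seed, {
    z <- stats::rnorm(n)
    e1 <- stats::rnorm(n)
    e2 <- stats::rnorm(n)
    if (exact) {
      std <- function(v) (v - mean(v)) / stats::sd(v)
      z <- std(z)
      # residualize e2 against z -> exactly zero sample correlation with z
      e2c <- e2 - mean(e2)
      e2p <- std(e2c - z * (sum(e2c * z) / sum(z * z)))
      a <- z
      b <- target_r * z + sqrt(max(0, 1 - target_r^2)) * e2p
    } else {
      s <- sqrt(abs(target_r))
      a <- s * z + sqrt(1 - s^2) * e1
      b <- sign(target_r) * s * z + sqrt(1 - s^2) * e2
      if (target_r == 0) { a <- e1; b <- e2 }
    }
    ch_a <- mean_intensity + sd_intensity * a
    ch_b <- mean_intensity + sd_intensity * b
    if (clip) {
      ch_a <- pmax(ch_a, 0)
      ch_b <- pmax(ch_b, 0)
    }
    image_pair(matrix(ch_a, shape[1], shape[2]),
               matrix(ch_b, shape[1], shape[2]),
               target_r = target_r)
  })
}
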