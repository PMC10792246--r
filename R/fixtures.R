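# A "study-like" fixture: 51 query variants (45 HGMD + 5 novel + 1
# literature), 5 characterized controls, 4 efflux experiments, a 29-species
# vertebrate alignment with 10 conservation-supported calibration variants,
# treatment arms and image pairs. Only the variant names printed in the
# source study are real; the remaining panel members are synthetic stand-ins
# whose positions are chosen in the extracellular domains but outside the
# gateway interval and the central annulus, so domain bookkeeping matches the
# printed counts.

#' The fixture's variant panel
#'
#' Returns the named variant sets used by [make_fixtures()]: the 12
#' loss-of-function variants, the 10 conservation-calibration variants, the 7
#' gateway-domain variants, the literature variant, the pathogenic and
#' negative controls, plus the synthetic stand-ins that pad the panel to 51
#' query variants.
#'
#' @return named list of character vectors of HGVS p. strings.
#' @export
abca1_panel <- function() {
  list(
    lof = c("p.E284K", "p.R306C", "p.Y482C", "p.T483P", "p.L510R",
            "p.R579Q", "p.G616V", "p.Q621R", "p.G790D", "p.L1379F",
            "p.H1600R", "p.R1615W"),
    calibration = c("p.R130K", "p.D176N", "p.R219K", "p.M233V", "p.P250L",
                    "p.V380I", "p.V589I", "p.T774P", "p.T1427M",
                    "p.R1587K"),
    gateway = c("p.N567Y", "p.D571G", "p.D575G", "p.R579Q", "p.D585E",
                "p.V589I", "p.G592C"),
    literature = "p.Y793C",
    pathogenic_controls = c("p.R587W", "p.W590S", "p.C1477R", "p.Y1767D"),
    negative_control = "p.K939M",
    # synthetic stand-ins (not printed in the study); ECD positions avoiding
    # the gateway interval (564-592) and the central annulus
    synthetic = c("p.A101T", "p.S145F", "p.G162R", "p.L197P", "p.D243N",
                  "p.T268I", "p.E327K", "p.R340W", "p.V412M", "p.N442S",
                  "p.P466L", "p.F495S", "p.K528E", "p.I551T", "p.Q603H",
                  "p.S628C", "p.E635D", "p.T1402A", "p.R1448C", "p.G1478S",
                  "p.L1522F", "p.D1561Y", "p.M1634V")
  )
}

# ground-truth relative activities (% of WT) for the fixture
.fixture_activities <- function() {
  panel <- abca1_panel()
  act <- c(
    # loss-of-function, all below 50
    p.E284K = 20, p.R306C = 25, p.Y482C = 22, p.T483P = 30, p.L510R = 8,
    p.R579Q = 35, p.G616V = 28, p.Q621R = 40, p.G790D = 10, p.L1379F = 38,
    p.H1600R = 15, p.R1615W = 32,
    # calibration variants; the three lowest reproduce the printed 79/80/82
    p.R130K = 79, p.P250L = 80, p.V589I = 82, p.D176N = 95, p.R219K = 101,
    p.M233V = 88, p.V380I = 110, p.T774P = 97, p.T1427M = 85, p.R1587K = 93,
    # non-LOF gateway variants: intermediate activity
    p.N567Y = 60, p.D571G = 65, p.D575G = 70, p.D585E = 58, p.G592C = 72,
    p.Y793C = 68,
    # controls: the strongest pathogenic control anchors the 50% cutoff
    p.R587W = 30, p.W590S = 50, p.C1477R = 20, p.Y1767D = 25, p.K939M = 5
  )
  synth <- panel$synthetic
  synth_act <- c(82, 95, 55, 88, 102, 63, 91, 78, 85, 99, 58, 93, 86, 71,
                 105, 89, 66, 96, 54, 84, 92, 75, 98)
  act[synth] <- synth_act
  act
}

.fixture_support <- function() {
  c(p.R130K = 5, p.D176N = 4, p.R219K = 6, p.M233V = 3, p.P250L = 4,
    p.V380I = 5, p.V589I = 3, p.T774P = 4, p.T1427M = 3, p.R1587K = 5,
    # sub-threshold supports: present in some species but not "more than two"
    p.E284K = 1, p.N567Y = 2, p.Y793C = 0)
}

#' Build the study-like synthetic fixture
#'
#' Generates every input the pipeline consumes, with ground truth: a variant
#' list (51 query variants: 45 HGMD-style, 5 novel, 1 literature; 4
#' pathogenic controls; 1 negative control), a 4-experiment efflux plate, a
#' 29-species alignment in which exactly the 10 calibration variants exceed
#' the conservation rule, 3-experiment treatment arms (epoxomicin, 4-PBA,
#' ApoA1) for the loss-of-function variants and controls, densitometry and
#' surface tables, and image pairs at generative correlations
#' 0.26 / 0.12 / 0.11 / 0.01 (3 experiments x 3 replicates each).
#'
#' @param out_dir optional directory; when given, every artifact is written
#'   as plain text (TSV/FASTA/JSON, images as whitespace matrices).
#' @param seed integer seed; the single seed fans out to per-stage
#'   substreams.
#' @param image_shape pixel dimensions of each simulated image.
#' @return (invisibly, when writing) a list with elements `variants`,
#'   `config`, `wells`, `treat` (per-arm well tables), `blots`, `surface`,
#'   `msa`, `images`, `image_manifest`, `truth`.
#' @export
make_fixtures <- function(out_dir = NULL, seed = 1L,
                          image_shape = c(64L, 64L)) {
  panel <- abca1_panel()
  act <- .fixture_activities()
  queries <- unique(c(panel$lof, panel$calibration, panel$gateway,
                      panel$literature, panel$synthetic))
  stopifnot(length(queries) == 51L)
  source <- rep("hgmd", length(queries))
  source[queries %in% panel$literature] <- "literature"
  source[queries %in% panel$synthetic[1:5]] <- "novel"
  variants <- rbind(
    data.frame(hgvs_p = queries, role = "query", source = source,
               stringsAsFactors = FALSE),
    data.frame(hgvs_p = panel$pathogenic_controls, role = "pathogenic_control",
               source = "control", stringsAsFactors = FALSE),
    data.frame(hgvs_p = panel$negative_control, role = "negative_control",
               source = "control", stringsAsFactors = FALSE)
  )
  variants$true_activity <- unname(act[variants$hgvs_p])
  stopifnot(!anyNA(variants$true_activity))

  # protein/surface ground truth: LOF mostly degraded; one LOF accumulates
  all_nms <- c("WT", names(act))
  lvl <- stats::setNames(rep(1, length(all_nms)), all_nms)
  lvl[panel$lof] <- c(0.5, 0.55, 0.5, 0.6, 0.35, 0.65, 1.6, 1.0, 0.4, 0.7,
                      0.45, 0.6)
  lvl[panel$pathogenic_controls] <- c(0.5, 0.7, 0.6, 0.6)
  surf <- stats::setNames(rep(1, length(all_nms)), all_nms)
  surf[panel$lof] <- c(0.45, 0.5, 0.4, 0.5, 0.05, 0.5, 0.35, 0.45, 0.1,
                       0.5, 0.15, 0.4)
  surf[panel$pathogenic_controls] <- c(0.5, 1.0, 0.2, 0.2)

  lof_ctrl <- c(panel$lof, panel$pathogenic_controls,
                panel$negative_control)
  epox_act <- stats::setNames(rep(1, length(lof_ctrl) + 1),
                              c("WT", lof_ctrl))
  epox_act[c("p.E284K", "p.R306C", "p.Y482C")] <- 1.6
  epox_act["p.G790D"] <- 0.7            # efflux drops despite more protein
  pba_act <- stats::setNames(rep(1, length(lof_ctrl) + 1), c("WT", lof_ctrl))
  pba_act[c("p.E284K", "p.R306C", "p.Y482C", "p.T483P", "p.R579Q",
            "p.Q621R", "p.L1379F")] <- 1.6
  pba_act[c("p.R587W", "p.W590S", "p.Y1767D")] <- 1.4
  pba_surf <- stats::setNames(rep(2, length(lof_ctrl) + 1), c("WT", lof_ctrl))
  pba_surf[c("p.L510R", "p.G616V", "p.H1600R", "p.R1615W")] <- c(3, 5, 6, 8)
  pba_surf["p.G790D"] <- 1
  apoa1_surf <- stats::setNames(rep(1, length(lof_ctrl) + 1),
                                c("WT", lof_ctrl))
  apoa1_surf["WT"] <- 1.5               # the 50% stabilization of the WT
  apoa1_surf[c("p.R306C", "p.Y482C", "p.R579Q", "p.Q621R", "p.L1379F",
               "p.C1477R")] <- 1.4
  treatment_effects <- list(
    epoxomicin = lapply(stats::setNames(names(epox_act), names(epox_act)),
                        function(nm) c(total = 2, surface = 2,
                                       activity = unname(epox_act[nm]))),
    pba_4 = lapply(stats::setNames(names(pba_act), names(pba_act)),
                   function(nm) c(total = 2,
                                  surface = unname(pba_surf[nm]),
                                  activity = unname(pba_act[nm]))),
    apoa1 = lapply(stats::setNames(names(apoa1_surf), names(apoa1_surf)),
                   function(nm) c(total = 1,
                                  surface = unname(apoa1_surf[nm]),
                                  activity = 1))
  )

  config <- sim_config(
    seed = seed, n_experiments = 4L,
    constructs = data.frame(name = variants$hgvs_p,
                            activity = variants$true_activity),
    protein_levels = lvl, surface_levels = surf,
    treatment_effects = treatment_effects
  )
  wells <- simulate_plate(config)

  # treatment arms: 3 independent experiments, LOF variants + controls only
  treat_cfg <- sim_config(
    seed = stage_seed(seed, "treatments"), n_experiments = 3L,
    constructs = data.frame(name = lof_ctrl,
                            activity = unname(act[lof_ctrl])),
    protein_levels = lvl[c("WT", lof_ctrl)],
    surface_levels = surf[c("WT", lof_ctrl)],
    treatment_effects = treatment_effects
  )
  treat <- list(
    mock_treated = simulate_plate(treat_cfg, "mock_treated"),
    epoxomicin = simulate_plate(treat_cfg, "epoxomicin"),
    pba_4 = simulate_plate(treat_cfg, "pba_4")
  )
  blots <- simulate_blots(treat_cfg,
                          conditions = c("mock_treated", "epoxomicin",
                                         "pba_4"))
  surface <- simulate_surface(treat_cfg,
                              conditions = c("mock_treated", "apoa1"))

  # every panel variant appears with an explicit support count (0 by
  # default) so the human row carries its reference residue and no variant
  # can pick up spurious conservation from the random background
  support <- stats::setNames(rep(0L, nrow(variants)), variants$hgvs_p)
  support[names(.fixture_support())] <- .fixture_support()
  msa <- simulate_msa(n_species = 29L, variant_support = as.list(support),
                      seed = stage_seed(seed, "msa"), seq_length = 1800L)

  coloc_truth <- c(WT = 0.26, p.H1600R = 0.12, p.C1477R = 0.11,
                   p.L510R = 0.01)
  manifest <- expand.grid(experiment = 1:3, replicate = 1:3,
                          construct = names(coloc_truth),
                          stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  manifest$target_r <- coloc_truth[manifest$construct]
  images <- lapply(seq_len(nrow(manifest)), function(i) {
    simulate_image_pair(manifest$target_r[i], shape = image_shape,
                        seed = stage_seed(seed, "images") + i)
  })

  truth <- list(
    seed = seed,
    activities = as.list(act),
    classes = as.list(as.character(
      classify_activity(act, threshold_set(50, 80)))),
    coloc = as.list(coloc_truth),
    epoxomicin_responders = names(epox_act)[epox_act > 1],
    pba_responders = names(pba_act)[pba_act > 1],
    apoa1_responders = names(apoa1_surf)[apoa1_surf > 1],
    calibration_supported = names(which(.fixture_support() > 2))
  )

  fx <- list(variants = variants, config = config, wells = wells,
             treat = treat, blots = blots, surface = surface, msa = msa,
             images = images, image_manifest = manifest, truth = truth,
             seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_variant_table(variants, file.path(out_dir, "variants.tsv"))
    write_well_table(wells, file.path(out_dir, "wells.tsv"))
    for (arm in names(treat)) {
      write_well_table(treat[[arm]],
                       file.path(out_dir, paste0("wells_", arm, ".tsv")))
    }
    write_blot_table(blots, file.path(out_dir, "blots.tsv"))
    write_surface_table(surface, file.path(out_dir, "surface.tsv"))
    write_msa(msa, file.path(out_dir, "msa.fasta"))
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    manifest$file_a <- sprintf("images/img%02d_a.txt", seq_len(nrow(manifest)))
    manifest$file_b <- sprintf("images/img%02d_b.txt", seq_len(nrow(manifest)))
    for (i in seq_len(nrow(manifest))) {
      write_image_matrix(images[[i]]$channel_a,
                         file.path(out_dir, manifest$file_a[i]))
      write_image_matrix(images[[i]]$channel_b,
                         file.path(out_dir, manifest$file_b[i]))
    }
    write_tsv(manifest, file.path(out_dir, "images.tsv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    fx$image_manifest <- manifest
    return(invisible(fx))
  }
  fx
}
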