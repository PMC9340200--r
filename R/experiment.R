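# Orchestration of the full study design on synthetic cohorts: simulate ->
# QC -> PC spaces (+ projections) -> GWASs -> PRSs -> validation grids and
# decomposition tables.

#' Build an experiment configuration
#'
#' The default configuration is the study-design emulation preset at desk
#' scale: the discovery cohort and its held-out same-cohort target mix four
#' European-like subpopulations on an ancestry cline (A1-A4, pairwise FST
#' 0.02); a genetically close second target cohort mixes two further cline
#' subpopulations (B1-B2); each cohort has an independent cohort-specific
#' panel; the external European-like panel shares exactly one subpopulation
#' with each cohort plus one of its own (A4/B1/C1), spanning the cohorts'
#' internal structure only partially; a non-European-like panel (N1-N2,
#' FST to the cline about 0.11) shares no drift with them; the all-reference
#' panel is the union of the last two, emulating a public reference dataset.
#' One structured (height-like) and one non-structured (BMI-like) trait are
#' simulated for the cohort samples; reference-panel individuals contribute
#' genotypes only.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory for `run_experiment()`.
#' @param scale Multiplier applied to all role sizes and the variant count.
#' @param n_variants Number of simulated variants.
#' @param n_causal Causal variants per trait.
#' @param sizes Named role sizes (discovery, target_same, target_other,
#'   panel_same, panel_other, panel_eur, panel_neur).
#' @param divergence Named per-population Balding-Nichols divergences.
#' @param ancestry_shifts Named per-population ancestry-cline shifts.
#' @param trait_structured,trait_nonstructured [trait_model()] objects.
#' @param n_pcs Principal components used for adjustment (GWAS and
#'   validation).
#' @param clump List with `r2_max`, `p_max`, `window_kb`.
#' @param thresholds P-value threshold grid for score construction.
#' @param missing_rate Per-variant missing-dosage rate.
#' @param ld Optional block-LD settings (`list(rho=, block_size=)`).
#' @param chrom_lengths Chromosome spans in base pairs.
#' @param write_plink Also write the simulated genotypes as PLINK
#'   bed/bim/fam (off by default; the TSV outputs carry the analysis).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(
    seed = 1,
    out_dir = tempfile("prstrat_run_"),
    scale = 1,
    n_variants = 8000,
    n_causal = 400,
    sizes = c(discovery = 6000, target_same = 2500, target_other = 2500,
              panel_same = 800, panel_other = 800, panel_eur = 400,
              panel_neur = 800),
    divergence = c(A1 = 0.02, A2 = 0.02, A3 = 0.02, A4 = 0.02,
                   B1 = 0.02, B2 = 0.02, C1 = 0.02, N1 = 0.2, N2 = 0.2),
    ancestry_shifts = c(A1 = 0, A2 = 1, A3 = 2, A4 = 3, B1 = 2, B2 = 3,
                        C1 = 2, N1 = 0, N2 = 0),
    trait_structured = trait_model(
      heritability = 0.3, n_causal = n_causal, structure_effect = 0.05,
      covariate_effects = c(age = 0.1, sex = 0.1, batch = 0.05)),
    trait_nonstructured = trait_model(
      heritability = 0.2, n_causal = n_causal, structure_effect = 0,
      covariate_effects = c(age = 0.1, sex = 0.1, batch = 0.05)),
    n_pcs = 20,
    clump = list(r2_max = 0.05, p_max = 1, window_kb = 1000),
    thresholds = prs_threshold_grid(),
    missing_rate = 0,
    ld = NULL,
    chrom_lengths = c(`1` = 1.2e8, `2` = 1.2e8),
    write_plink = FALSE) {
  sizes <- stats::setNames(pmax(4L, as.integer(round(sizes * scale))),
                           names(sizes))
  n_variants <- max(50L, as.integer(round(n_variants * scale)))
  n_causal <- min(as.integer(n_causal), n_variants)
  req <- c("discovery", "target_same", "target_other", "panel_same",
           "panel_other", "panel_eur", "panel_neur")
  if (!all(req %in% names(sizes))) {
    stop("sizes must name: ", paste(req, collapse = ", "))
  }
  stopifnot(inherits(trait_structured, "trait_model"),
            inherits(trait_nonstructured, "trait_model"))
  structure(list(
    seed = as.integer(seed), out_dir = out_dir, scale = scale,
    n_variants = n_variants, n_causal = n_causal, sizes = sizes,
    divergence = divergence, ancestry_shifts = ancestry_shifts,
    trait_structured = trait_structured,
    trait_nonstructured = trait_nonstructured,
    n_pcs = n_pcs, clump = clump, thresholds = thresholds,
    missing_rate = missing_rate, ld = ld, chrom_lengths = chrom_lengths,
    write_plink = isTRUE(write_plink)
  ), class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("experiment_config\n")
  cat("  seed:", x$seed, "  variants:", x$n_variants,
      " causal:", x$n_causal, "\n")
  cat("  sizes:", paste(sprintf("%s=%d", names(x$sizes), x$sizes),
                        collapse = " "), "\n")
  cat("  out_dir:", x$out_dir, "\n")
  invisible(x)
}

#' Write/read an experiment configuration as YAML
#'
#' The YAML round trip is lossless for every analysis parameter. The output
#' directory is a runtime location, not an analysis parameter: it is omitted
#' from the file (keeping run manifests byte-identical across directories)
#' and supplied again when reading.
#'
#' @param config An `experiment_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$out_dir <- NULL
  x$trait_structured <- unclass(x$trait_structured)
  x$trait_nonstructured <- unclass(x$trait_nonstructured)
  ## yaml drops names of atomic vectors; named parameters go out as maps
  for (f in c("sizes", "divergence", "ancestry_shifts", "chrom_lengths")) {
    x[[f]] <- as.list(x[[f]])
  }
  for (t in c("trait_structured", "trait_nonstructured")) {
    x[[t]]$covariate_effects <- as.list(x[[t]]$covariate_effects)
  }
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @param out_dir Output directory to attach to the configuration read back.
#' @export
read_config <- function(path, out_dir = tempfile("prstrat_run_")) {
  x <- yaml::read_yaml(path)
  as_named <- function(v) unlist(v)
  tm <- function(t) trait_model(
    heritability = t$heritability, n_causal = t$n_causal,
    structure_effect = t$structure_effect,
    covariate_effects = as_named(t$covariate_effects),
    noise_sd = t$noise_sd)
  experiment_config(
    seed = x$seed, out_dir = out_dir, scale = 1,
    n_variants = x$n_variants, n_causal = x$n_causal,
    sizes = as_named(x$sizes), divergence = as_named(x$divergence),
    ancestry_shifts = as_named(x$ancestry_shifts),
    trait_structured = tm(x$trait_structured),
    trait_nonstructured = tm(x$trait_nonstructured),
    n_pcs = x$n_pcs, clump = x$clump,
    thresholds = unlist(x$thresholds), missing_rate = x$missing_rate,
    ld = x$ld, chrom_lengths = as_named(x$chrom_lengths),
    write_plink = x$write_plink)
}

# Stage seeds derived deterministically from the master seed (kept within
# 32-bit integer range).
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 2654435 + k * 40503) %% .Machine$integer.max)
}

# Integer role-by-population allocation for the emulation design. The first
# cohort carries four subpopulations (multi-dimensional internal structure);
# the second cohort two of its own; the external European-like panel shares
# exactly one subpopulation with each cohort plus one of its own, so it spans
# the cohorts' internal structure only partially.
role_population_counts <- function(sizes) {
  parts <- function(n, k) {
    b <- floor(n / k)
    c(rep(b, k - 1), n - (k - 1) * b)
  }
  quarter_A <- function(n) stats::setNames(parts(n, 4),
                                           c("A1", "A2", "A3", "A4"))
  half_B <- function(n) stats::setNames(parts(n, 2), c("B1", "B2"))
  counts <- list(
    discovery = quarter_A(sizes[["discovery"]]),
    target_same = quarter_A(sizes[["target_same"]]),
    panel_same = quarter_A(sizes[["panel_same"]]),
    target_other = half_B(sizes[["target_other"]]),
    panel_other = half_B(sizes[["panel_other"]]),
    panel_eur = stats::setNames(parts(sizes[["panel_eur"]], 3),
                                c("A4", "B1", "C1")),
    panel_neur = stats::setNames(parts(sizes[["panel_neur"]], 2),
                                 c("N1", "N2"))
  )
  counts
}

#' Run the full synthetic experiment
#'
#' Executes the complete pipeline: genotype and trait simulation, role
#' splits, variant QC, construction of the five PC spaces (cohort-specific
#' for each target cohort, all-reference, European-like, non-European-like)
#' with projection of discovery and targets, five GWASs per trait on the
#' discovery cohort (no-PC control plus four PC adjustments), per target
#' cohort five clumped and threshold-optimised polygenic scores, the 5 x 5
#' validation grid per trait and target, the six-model decomposition tables,
#' a genomic-inflation table, and a provenance manifest. All outputs are
#' deterministic given the configuration (byte-identical TSVs under the same
#' seed).
#'
#' @param config An [experiment_config()].
#' @return Object of class `experiment_result` (invisible components: grids,
#'   decomposition tables, lambda table, PRS metadata, paths).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  on_fail <- function(e) {
    stop(sprintf("experiment failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    stage <- "simulate"
    counts <- role_population_counts(config$sizes)
    pops <- names(config$divergence)
    n_per_pop <- stats::setNames(rep(0L, length(pops)), pops)
    for (ct in counts) n_per_pop[names(ct)] <- n_per_pop[names(ct)] + ct
    model <- pop_model(length(pops), fst = config$divergence,
                       n_variants = config$n_variants,
                       chrom_lengths = config$chrom_lengths,
                       pop_labels = pops)
    geno <- simulate_genotypes(model, n_per_pop[pops],
                               seed = stage_seed(config$seed, 1),
                               missing_rate = config$missing_rate,
                               ld = config$ld)
    samples <- make_samples(geno, seed = stage_seed(config$seed, 2),
                            ancestry_shifts = config$ancestry_shifts)

    stage <- "split"
    sizes_spec <- list()
    for (role in names(counts)) {
      for (p in names(counts[[role]])) {
        sizes_spec[[paste(role, p, sep = ".")]] <-
          list(n = counts[[role]][[p]], populations = p)
      }
    }
    raw_split <- split_cohorts(samples, sizes_spec,
                               seed = stage_seed(config$seed, 3))
    split <- lapply(stats::setNames(names(counts), names(counts)), function(r) {
      sort(unlist(raw_split[grep(paste0("^", r, "\\."), names(raw_split))],
                  use.names = FALSE))
    })
    split$panel_all <- sort(c(split$panel_eur, split$panel_neur))
    roles_disjoint <- c("discovery", "target_same", "target_other",
                        "panel_same", "panel_other", "panel_eur", "panel_neur")
    for (i in seq_along(roles_disjoint)) {
      for (j in seq_len(i - 1)) {
        ov <- intersect(split[[roles_disjoint[i]]], split[[roles_disjoint[j]]])
        if (length(ov) > 0) {
          stop("cohort roles overlap: ", roles_disjoint[i], "/",
               roles_disjoint[j])
        }
      }
    }

    stage <- "traits"
    cohort_ids <- sort(c(split$discovery, split$target_same,
                         split$target_other))
    geno_cohorts <- subset_geno(geno, samples = cohort_ids)
    geno_cohorts$freq <- NULL
    samp_cohorts <- samples[match(cohort_ids, samples$sample_id), ]
    ## ancestry score restandardised over the phenotyped cohorts
    samp_cohorts$ancestry_score <- as.numeric(scale(
      config$ancestry_shifts[samp_cohorts$population]))
    trait_height <- simulate_trait(geno_cohorts, samp_cohorts,
                                   config$trait_structured,
                                   seed = stage_seed(config$seed, 4))
    trait_bmi <- simulate_trait(geno_cohorts, samp_cohorts,
                                config$trait_nonstructured,
                                seed = stage_seed(config$seed, 5))
    traits <- list(height_like = trait_height, bmi_like = trait_bmi)
    write_pheno(samp_cohorts,
                list(trait_height_like = trait_height,
                     trait_bmi_like = trait_bmi),
                file.path(config$out_dir, "phenotypes.tsv"))
    for (tn in names(traits)) {
      utils::write.table(attr(traits[[tn]], "causal_effects"),
                         file.path(config$out_dir,
                                   paste0("truth_", tn, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_config(config, file.path(config$out_dir, "config.yaml"))
    if (config$write_plink) {
      write_plink(geno, file.path(config$out_dir, "genotypes"))
    }
    rm(geno_cohorts)
    gc(FALSE)

    stage <- "qc"
    take <- function(ids) {
      g <- subset_geno(geno, samples = ids)
      g$freq <- NULL
      g
    }
    qc <- function(g) filter_variants(g)
    disc_raw <- take(split$discovery)
    tgt_raw <- list(same = take(split$target_same),
                    other = take(split$target_other))
    panels_raw <- lapply(split[c("panel_same", "panel_other", "panel_all",
                                 "panel_eur", "panel_neur")], take)
    rm(geno)
    gc(FALSE)
    disc_qc <- qc(disc_raw)
    tgt_same_qc <- qc(tgt_raw$same)
    tgt_other_qc <- qc(tgt_raw$other)
    utils::write.table(as.data.frame(disc_qc$report),
                       file.path(config$out_dir, "qc_discovery.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "pc_spaces"
    K <- config$n_pcs
    spaces <- list(
      cohort_same = build_pc_space(qc(panels_raw$panel_same)$genotypes, K = K),
      cohort_other = build_pc_space(qc(panels_raw$panel_other)$genotypes, K = K),
      allref = build_pc_space(qc(panels_raw$panel_all)$genotypes, K = K),
      eurlike = build_pc_space(qc(panels_raw$panel_eur)$genotypes, K = K),
      neurlike = build_pc_space(qc(panels_raw$panel_neur)$genotypes, K = K)
    )
    rm(panels_raw)
    gc(FALSE)
    proj <- function(space, cohort_geno, label) {
      project_samples(space, cohort_geno, label = label)
    }
    pcs_disc <- list(
      cohort = proj(spaces$cohort_same, disc_raw, "cohort"),
      allref = proj(spaces$allref, disc_raw, "allref"),
      eurlike = proj(spaces$eurlike, disc_raw, "eurlike"),
      neurlike = proj(spaces$neurlike, disc_raw, "neurlike")
    )
    rm(disc_raw)
    gc(FALSE)

    stage <- "gwas"
    disc_ids <- disc_qc$genotypes$samples$sample_id
    samp_disc <- samp_cohorts[match(disc_ids, samp_cohorts$sample_id), ]
    gwas_all <- list()
    lambda_rows <- list()
    for (tn in names(traits)) {
      y <- traits[[tn]][disc_ids]
      for (pcn in c("none", "cohort", "allref", "eurlike", "neurlike")) {
        pcs <- if (pcn == "none") NULL else pcs_disc[[pcn]]
        st <- run_gwas(disc_qc$genotypes, y, samp_disc, pcs = pcs,
                       n_pcs = config$n_pcs)
        gwas_all[[tn]][[pcn]] <- st
        lambda_rows[[length(lambda_rows) + 1]] <- data.frame(
          trait = tn, pc_set = pcn, lambda = attr(st, "lambda"),
          stringsAsFactors = FALSE)
      }
    }
    lambda_table <- do.call(rbind, lambda_rows)
    utils::write.table(
      transform(lambda_table, lambda = round(lambda, 6)),
      file.path(config$out_dir, "genomic_inflation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "prs_validation"
    prs_labels <- c(none = "PRS_0", cohort = "PRS_cohort",
                    allref = "PRS_allref", eurlike = "PRS_eurlike",
                    neurlike = "PRS_neurlike")
    pc_cols <- c(cohort = "PC_cohort", allref = "PC_allref",
                 eurlike = "PC_eurlike", neurlike = "PC_neurlike",
                 none = "PC_0")
    targets <- list(
      same = list(qc = tgt_same_qc, ids = split$target_same,
                  cohort_space = spaces$cohort_same),
      other = list(qc = tgt_other_qc, ids = split$target_other,
                   cohort_space = spaces$cohort_other)
    )
    rm(tgt_same_qc, tgt_other_qc)
    disc_qc$genotypes <- NULL
    gc(FALSE)
    grids <- list()
    decomps <- list()
    prs_meta <- list()
    for (tg in names(targets)) {
      tq <- targets[[tg]]$qc$genotypes
      tids <- tq$samples$sample_id
      samp_t <- samp_cohorts[match(tids, samp_cohorts$sample_id), ]
      raw_t <- tgt_raw[[tg]]
      pcs_t <- list(
        cohort = proj(targets[[tg]]$cohort_space, raw_t, "cohort"),
        allref = proj(spaces$allref, raw_t, "allref"),
        eurlike = proj(spaces$eurlike, raw_t, "eurlike"),
        neurlike = proj(spaces$neurlike, raw_t, "neurlike")
      )
      pcs_t <- lapply(pcs_t, function(p) p[tids, , drop = FALSE])
      for (p in names(pcs_t)) {
        attr(pcs_t[[p]], "source_space") <- pc_cols[[p]]
        class(pcs_t[[p]]) <- c("pc_coords", "matrix")
      }
      rm(raw_t)
      tgt_raw[[tg]] <- NULL
      Xs_t <- standardize_dosage(tq$dosage)
      gc(FALSE)
      for (tn in names(traits)) {
        y <- traits[[tn]][tids]
        profiles <- list()
        for (pcn in names(prs_labels)) {
          st <- gwas_all[[tn]][[pcn]]
          clumped <- clump_variants(st, tq,
                                    r2_max = config$clump$r2_max,
                                    p_max = config$clump$p_max,
                                    window_kb = config$clump$window_kb,
                                    X = Xs_t)
          prof <- select_best_threshold(tq, y, samp_t, st, clumped,
                                        pcs = NULL,
                                        thresholds = config$thresholds)
          prof$label <- prs_labels[[pcn]]
          profiles[[prs_labels[[pcn]]]] <- prof
          prs_meta[[length(prs_meta) + 1]] <- data.frame(
            target = tg, trait = tn, prs = prs_labels[[pcn]],
            chosen_threshold = prof$chosen_threshold,
            n_snps = prof$n_snps, stringsAsFactors = FALSE)
        }
        grid <- run_grid(y, profiles, samp_t,
                         stats::setNames(pcs_t, pc_cols[names(pcs_t)]),
                         n_pcs = config$n_pcs)
        grids[[paste(tg, tn, sep = ".")]] <- grid
        write_grid(grid, file.path(config$out_dir,
                                   sprintf("grid_%s_%s", tg, tn)))
        dec <- do.call(rbind, lapply(names(profiles), function(pl) {
          d <- run_decomposition(y, profiles[[pl]], pcs_t$cohort, samp_t,
                                 n_pcs = config$n_pcs, n_tests = 10)
          cbind(prs = pl, as.data.frame(d))
        }))
        decomps[[paste(tg, tn, sep = ".")]] <- dec
        utils::write.table(
          transform(dec, r2 = signif(r2, 8), f = signif(f, 8),
                    p = signif(p, 8)),
          file.path(config$out_dir,
                    sprintf("decomposition_%s_%s.tsv", tg, tn)),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
      rm(Xs_t, tq)
      targets[[tg]]$qc <- NULL
      gc(FALSE)
    }
    meta <- do.call(rbind, prs_meta)
    utils::write.table(meta, file.path(config$out_dir, "prs_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "manifest"
    manifest <- list(
      package = "prstrat",
      package_version = as.character(utils::packageVersion("prstrat")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      stage_seeds = sapply(1:5, function(k) stage_seed(config$seed, k)),
      sizes = as.list(config$sizes),
      n_variants = config$n_variants,
      config_md5 = unname(tools::md5sum(file.path(config$out_dir,
                                                  "config.yaml")))
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

    structure(list(
      config = config, split = split, grids = grids, decomps = decomps,
      lambda_table = lambda_table, prs_meta = meta,
      qc_report = disc_qc$report, out_dir = config$out_dir
    ), class = "experiment_result")
  }, error = on_fail)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result in", x$out_dir, "\n\n")
  cat("Genomic inflation by GWAS version:\n")
  print(transform(x$lambda_table, lambda = round(lambda, 3)),
        row.names = FALSE)
  for (g in names(x$grids)) {
    cat(sprintf("\nBest validation cell [%s]: PRS %s | PC %s\n", g,
                x$grids[[g]]$best_cell[["prs"]],
                x$grids[[g]]$best_cell[["pc"]]))
  }
  invisible(x)
}
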