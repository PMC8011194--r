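#' Pipeline configuration
#'
#' Assembles and validates the settings for [run_pipeline()]. Configurations
#' round-trip losslessly through JSON ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param input path to the genotype file.
#' @param format `"csv"` or `"spagedi"`.
#' @param coord_system `"planar"` or `"geographic"`.
#' @param out_dir output directory for reports and the manifest.
#' @param min_typed minimum fraction of typed loci per sample.
#' @param dedupe drop the later member of each exact-duplicate pair.
#' @param grid optional list `list(cell = degrees, max = count)` enabling
#'   spatial grid subsampling (geographic coordinates only).
#' @param k_max maximum number of clusters tried.
#' @param n_starts EM restarts per K.
#' @param q_threshold admixture threshold on the posterior membership.
#' @param ar_k gene copies for allelic richness (NULL = automatic).
#' @param n_perm permutations for the Fi, slope and allele-size tests.
#' @param fn_radius neighbourhood radius in meters.
#' @param density_per_ha named list/vector: census adult density (per ha)
#'   per cluster label (user-supplied; never inferred from coordinates).
#' @param de_fractions fractions of density used as De scenarios.
#' @param range_factor regression upper bound multiple (20 or 100).
#' @param mu mutation rate for the dispersal validity warning (optional).
#' @param selfing run the selfing-rate stage.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, format = "csv", coord_system = "planar",
                            out_dir = "sgsd_run", min_typed = 0.6,
                            dedupe = TRUE, grid = NULL, k_max = 10L,
                            n_starts = 20L, q_threshold = 0.8, ar_k = NULL,
                            n_perm = 10000L, fn_radius = 100,
                            density_per_ha = NULL,
                            de_fractions = c(1 / 2, 1 / 4, 1 / 10),
                            range_factor = 20, mu = NULL, selfing = TRUE,
                            seed = 1L) {
  stopifnot(format %in% c("csv", "spagedi"),
            coord_system %in% c("planar", "geographic"),
            min_typed > 0, min_typed <= 1, q_threshold > 0, q_threshold <= 1)
  structure(list(input = input, format = format,
                 coord_system = coord_system, out_dir = out_dir,
                 min_typed = min_typed, dedupe = dedupe, grid = grid,
                 k_max = as.integer(k_max), n_starts = as.integer(n_starts),
                 q_threshold = q_threshold, ar_k = ar_k,
                 n_perm = as.integer(n_perm), fn_radius = fn_radius,
                 density_per_ha = density_per_ha,
                 de_fractions = de_fractions, range_factor = range_factor,
                 mu = mu, selfing = selfing, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$grid <- if (!is.null(x$grid)) as.list(x$grid)
  do.call(pipeline_config, x[!vapply(x, is.null, logical(1))])
}

# deterministic per-stage seed derived from the global seed
stage_seed <- function(seed, stage) {
  (seed * 2654435761 + sum(utf8ToInt(stage)) * 97) %% 2147483647 + 1
}

#' Run the full analysis pipeline
#'
#' Executes, in the study's order: import, min-typed-loci QC, duplicate
#' removal, optional spatial grid subsampling, EM clustering with K
#' selection and the admixture threshold, then per-cluster diversity,
#' pairwise differentiation, spatial genetic structure (plus an "ALL"
#' analysis over every assigned sample), gene-dispersal estimation (one
#' estimate per De fraction per group with a configured density), and
#' selfing rates. Writes CSV reports, a JSON manifest with seeds and
#' stage-by-stage sample counts, and a plain-text log. A failing stage is
#' recorded in the manifest; independent later stages still run.
#'
#' @param config a [pipeline_config()].
#' @return The run directory path, invisibly; the manifest as attribute
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "log.txt")
  cat("", file = logf)
  logmsg <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    cat(msg, "\n", file = logf, append = TRUE)
  }
  manifest <- list(package_version = as.character(utils::packageVersion("sgsd")),
                   seed = config$seed, stages = list(), errors = list())
  note_stage <- function(name, n_in, n_out) {
    manifest$stages[[name]] <<- list(n_in = n_in, n_out = n_out,
                                     n_removed = n_in - n_out)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$errors[[name]] <<- conditionMessage(e)
      logmsg("ERROR in ", name, ": ", conditionMessage(e))
      NULL
    })
  }

  logmsg("import ", config$input)
  tab <- read_genotypes(config$input, config$format, config$coord_system)
  note_stage("import", n_samples(tab), n_samples(tab))

  n0 <- n_samples(tab)
  tab <- filter_min_typed_loci(tab, config$min_typed)
  note_stage("min_typed", n0, n_samples(tab))
  logmsg("min-typed filter kept ", n_samples(tab), "/", n0)

  if (isTRUE(config$dedupe)) {
    n0 <- n_samples(tab)
    dup <- detect_duplicates(tab)
    if (nrow(dup) > 0L) {
      drop <- unique(dup$id2[dup$identical])
      tab <- subset_samples(tab, which(!tab$samples$sample_id %in% drop))
    }
    note_stage("dedupe", n0, n_samples(tab))
    logmsg("dedupe kept ", n_samples(tab), "/", n0)
  }

  if (!is.null(config$grid)) {
    n0 <- n_samples(tab)
    tab <- grid_subsample(tab, config$grid$cell, config$grid$max,
                          seed = stage_seed(config$seed, "grid"))
    note_stage("grid_subsample", n0, n_samples(tab))
    logmsg("grid subsample kept ", n_samples(tab), "/", n0)
  }

  sel <- run_stage("clustering", {
    sk <- select_k(tab, k_max = config$k_max, n_starts = config$n_starts,
                   seed = stage_seed(config$seed, "cluster"))
    utils::write.csv(sk$scores, file.path(config$out_dir, "k_scores.csv"),
                     row.names = FALSE)
    fit <- sk$fits[[sk$K]]
    qdf <- data.frame(sample_id = fit$ids, fit$q)
    names(qdf)[-1L] <- sprintf("q%d", seq_len(fit$K))
    utils::write.csv(qdf, file.path(config$out_dir, "memberships.csv"),
                     row.names = FALSE)
    thr <- apply_admixture_threshold(fit, tab, config$q_threshold)
    logmsg("chose K = ", sk$K, "; unassigned: ", length(thr$unassigned))
    list(K = sk$K, thr = thr)
  })
  assigned <- if (is.null(sel)) tab else sel$thr$table
  note_stage("admixture_threshold", n_samples(tab), n_samples(assigned))

  groups <- sort(unique(stats::na.omit(assigned$samples$group)))
  perm_seed <- stage_seed(config$seed, "perm")

  run_stage("diversity", {
    div <- diversity_summary(assigned, k = config$ar_k,
                             n_perm = config$n_perm, seed = perm_seed)
    utils::write.csv(div, file.path(config$out_dir, "table1_diversity.csv"),
                     row.names = FALSE)
    logmsg("diversity written for ", nrow(div), " groups")
  })

  run_stage("differentiation", {
    if (length(groups) < 2L) stop("need >= 2 groups")
    diff <- differentiation(assigned, groups, n_perm = config$n_perm,
                            seed = perm_seed)
    m <- diff$FST
    m[upper.tri(m)] <- diff$RST[upper.tri(diff$RST)]
    utils::write.csv(
      data.frame(group = rownames(m), round(m, 6), check.names = FALSE),
      file.path(config$out_dir, "table2_fst_rst.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(group = rownames(diff$pRST_p), round(diff$pRST_p, 6),
                 check.names = FALSE),
      file.path(config$out_dir, "table2_prst_p.csv"), row.names = FALSE)
    logmsg("differentiation written")
  })

  sgs_units <- c(stats::setNames(as.list(groups), groups), list(ALL = NULL))
  curves <- list(); sgs_rows <- list(); disp_rows <- list()
  for (nm in names(sgs_units)) {
    res <- run_stage(paste0("sgs_", nm), {
      sub <- if (is.null(sgs_units[[nm]])) assigned
             else subset_samples(assigned, group = sgs_units[[nm]])
      kin <- loiselle_kinship(sub)
      dm <- pairwise_distances(sub)
      sgs <- kinship_distance_analysis(kin, dm, n_perm = config$n_perm,
                                       seed = perm_seed,
                                       fn_radius = config$fn_radius)
      list(kin = kin, dm = dm,
           curve = cbind(group = nm, sgs$classes),
           row = data.frame(
             group = nm, n = n_samples(sub), n_pairs = sgs$n_pairs,
             b_log = sgs$b_log, F1 = sgs$F1, Fn = sgs$Fn, Sp = sgs$Sp,
             Sp_SE = sgs$Sp_SE, perm_p = sgs$perm_p))
    })
    if (!is.null(res)) {
      curves[[nm]] <- res$curve
      sgs_rows[[nm]] <- res$row
    }
    if (nm != "ALL" && !is.null(res) &&
        !is.null(config$density_per_ha[[nm]])) {
      rows <- run_stage(paste0("dispersal_", nm), {
        sc <- density_scenarios(config$density_per_ha[[nm]],
                                config$de_fractions)
        lapply(seq_len(nrow(sc)), function(i) {
          de <- estimate_sigma_g(res$kin, res$dm, sc$De_per_m2[i],
                                 range_factor = config$range_factor,
                                 fn_radius = config$fn_radius,
                                 mu = config$mu)
          data.frame(
            group = nm, fraction = sc$fraction[i],
            De_per_ha = sc$De_per_ha[i], sigma_g_m = de$sigma_g,
            Nb = de$Nb, iterations = de$iterations,
            converged = de$converged,
            flags = paste(de$flags, collapse = "; "))
        })
      })
      if (!is.null(rows)) disp_rows[[nm]] <- do.call(rbind, rows)
    }
  }
  if (length(sgs_rows) > 0L)
    utils::write.csv(do.call(rbind, sgs_rows),
                     file.path(config$out_dir, "sgs.csv"), row.names = FALSE)
  if (length(curves) > 0L)
    utils::write.csv(do.call(rbind, curves),
                     file.path(config$out_dir, "sgs_curves.csv"),
                     row.names = FALSE)
  if (length(disp_rows) > 0L)
    utils::write.csv(do.call(rbind, disp_rows),
                     file.path(config$out_dir, "dispersal.csv"),
                     row.names = FALSE)

  if (isTRUE(config$selfing)) {
    run_stage("selfing", {
      rows <- lapply(groups, function(g) {
        est <- selfing_with_jackknife(assigned, group = g)
        data.frame(group = g, g2 = est$g2, s_hat = est$s_hat, SE = est$SE,
                   n_loci = est$n_loci, significant = est$significant)
      })
      utils::write.csv(do.call(rbind, rows),
                       file.path(config$out_dir, "selfing.csv"),
                       row.names = FALSE)
      logmsg("selfing written")
    })
  }

  manifest$chosen_K <- if (!is.null(sel)) sel$K else NA
  manifest$groups <- groups
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  write_pipeline_config(config, file.path(config$out_dir, "config.json"))
  logmsg("done")
  out <- config$out_dir
  attr(out, "manifest") <- manifest
  invisible(out)
}
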