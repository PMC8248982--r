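## Orchestration: one-call pipeline over a dataset directory plus a
## plain-text/TSV report generator. The R functions are the interface;
## each stage is also callable on its own.

#' Pipeline run configuration
#'
#' @param data_dir dataset directory (layout of [generate_dataset()]:
#'   allele counts, sample sheet, weather, stations, recombination map,
#'   repeats BED).
#' @param out_dir results directory.
#' @param seed global seed; stages derive named sub-streams.
#' @param n_perms_glm,n_perms_rfm within-pair label permutations for the
#'   two seasonal scans (defaults 500 and 200).
#' @param q enrichment quantile (default 0.01).
#' @param quantiles concordance/LOO quantile grid.
#' @param n_perms_thermal permutations for the thermal-scan null.
#' @param thermal_limits,thermal_step scan range and step.
#' @param filter a [filter_config()].
#' @param stages character vector of stages to run, in dependency order.
#' @export
run_config <- function(data_dir, out_dir, seed = 1L,
                       n_perms_glm = 500L, n_perms_rfm = 200L, q = 0.01,
                       quantiles = default_quantile_grid(),
                       n_perms_thermal = 25000L,
                       thermal_limits = c(-5, 40), thermal_step = 0.1,
                       filter = filter_config(),
                       stages = c("filter", "seasonal", "regions",
                                  "concordance", "predictability", "thermal")) {
  structure(list(data_dir = data_dir, out_dir = out_dir, seed = as.integer(seed),
                 n_perms_glm = as.integer(n_perms_glm),
                 n_perms_rfm = as.integer(n_perms_rfm), q = q,
                 quantiles = quantiles,
                 n_perms_thermal = as.integer(n_perms_thermal),
                 thermal_limits = thermal_limits, thermal_step = thermal_step,
                 filter = filter, stages = stages),
            class = "run_config")
}

#' Run the seasonal-adaptation pipeline
#'
#' Stages run in dependency order: SNP filtering, seasonal scans (GLM +
#' RFM with their permutation nulls), inversion-region enrichment,
#' seasonal-clinal concordance (when the dataset carries clinal-only
#' samples), leave-one-out predictability, and the thermal-limit scan.
#' Every stage writes its TSV outputs as it completes, so a failure
#' preserves partial results; the run log and a JSON manifest record
#' seeds, thresholds and per-stage SNP counts.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat(sprintf("seasonscan %s | seed %d | %s\n",
              as.character(utils::packageVersion("seasonscan")),
              config$seed, format(Sys.time())), file = logf)
  res <- list()
  stage <- function(name, expr) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    msg(verbose, "[%s] running", name)
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e)
      stop_invalid("pipeline stage '%s' failed: %s (partial outputs kept in %s)",
                   name, conditionMessage(e), config$out_dir))
    log_line("stage %s done in %.1fs", name,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  dd <- config$data_dir
  tbl <- read_allele_counts(file.path(dd, "allele_counts.tsv"))
  sheet <- read_sample_sheet(file.path(dd, "samples.csv"))
  rmap_path <- file.path(dd, "recomb_map.csv")
  rmap <- if (file.exists(rmap_path)) read_recomb_map(rmap_path) else NULL
  rep_path <- file.path(dd, "repeats.bed")
  repeats <- if (file.exists(rep_path)) read_regions(rep_path, "repeats") else NULL
  log_line("input: %d SNPs x %d samples", n_snps(tbl), length(sample_ids(tbl)))

  res$filter <- stage("filter", {
    fr <- filter_snps(tbl, config$filter, repeats = repeats, rmap = rmap)
    log_line("filter: kept %d SNPs; removed: %s", n_snps(fr$table),
             paste(names(fr$removed), fr$removed, sep = "=", collapse = ", "))
    fr
  })
  tblf <- if (!is.null(res$filter)) res$filter$table else tbl
  pairs <- season_pairs(sheet)

  res$seasonal <- stage("seasonal", {
    g <- glm_seasonal(tblf, sheet, pairs)
    r <- rfm_seasonal(tblf, sheet, pairs)
    plan_g <- permute_plan(pairs, config$n_perms_glm,
                           substream_seed(config$seed, "glm_perms"))
    thr <- quantile(g$glm_p, config$q, na.rm = TRUE, names = FALSE)
    pg <- glm_permute(tblf, sheet, plan_g, pairs, thresholds = thr)
    enr_g <- quantile_enrichment(g$glm_p, q = config$q,
                                 perm_counts = pg$counts[, 1])
    plan_r <- permute_plan(pairs, config$n_perms_rfm,
                           substream_seed(config$seed, "rfm_perms"))
    perm_x2 <- rfm_permute(r, plan_r, tail = "up")
    thr_r <- quantile(-r$rfm_x2_up, config$q, na.rm = TRUE, names = FALSE)
    enr_r <- quantile_enrichment(-r$rfm_x2_up, threshold = thr_r,
                                 perm_counts = colSums(-perm_x2 <= thr_r))
    write_seasonal(g, r, file.path(config$out_dir, "seasonal.tsv"))
    write_vc(rbind(cbind(test = "glm", enr_g), cbind(test = "rfm", enr_r)),
             file.path(config$out_dir, "seasonal_enrichment.tsv"), "enrichment",
             sep = "\t")
    log_line("seasonal: GLM enrichment %.2f (p_perm %.4g), RFM enrichment %.2f (p_perm %.4g)",
             enr_g$enrichment, enr_g$p_perm, enr_r$enrichment, enr_r$p_perm)
    list(glm = g, rfm = r, enrich_glm = enr_g, enrich_rfm = enr_r,
         perm_x2 = perm_x2)
  })

  res$regions <- stage("regions", {
    region <- classify_region(tblf$snps$chrom, tblf$snps$pos)
    # region enrichment on the RFM statistic (its permutation matrix is
    # cheap at genome scale); larger X^2 = more seasonal, so negate
    re <- region_enrichment(-res$seasonal$rfm$rfm_x2_up,
                            -res$seasonal$perm_x2, region,
                            tblf$snps$chrom, q = config$q)
    write_vc(re, file.path(config$out_dir, "region_enrichment.tsv"),
             "region-enrichment", sep = "\t")
    list(region = region, enrichment = re)
  })

  has_clinal <- !is.null(sheet$role) && any(sheet$role == "clinal")
  res$concordance <- stage("concordance", {
    if (!has_clinal) {
      log_line("concordance: no clinal-only samples; skipped")
      return(NULL)
    }
    clin_ids <- sheet$sample_id[sheet$role == "clinal"]
    assert_disjoint_localities(sheet, c(pairs$spring_id, pairs$fall_id), clin_ids)
    cl <- glm_clinal(tblf, sheet, clin_ids)
    cc <- concordance_curve(res$seasonal$glm, cl, config$quantiles)
    region <- res$regions$region %||%
      classify_region(tblf$snps$chrom, tblf$snps$pos)
    cr <- concordance_by_region(res$seasonal$glm, cl, region, q = 0.05)
    write_vc(cl, file.path(config$out_dir, "clinal.tsv"), "clinal-result",
             sep = "\t")
    write_vc(cc, file.path(config$out_dir, "concordance_curve.tsv"),
             "concordance", sep = "\t")
    write_vc(cr, file.path(config$out_dir, "concordance_by_region.tsv"),
             "concordance-region", sep = "\t")
    list(clinal = cl, curve = cc, by_region = cr)
  })

  res$predictability <- stage("predictability", {
    loo <- leave_one_out(tblf, sheet, pairs, config$quantiles)
    write_vc(loo, file.path(config$out_dir, "predictability_scores.tsv"),
             "predictability", sep = "\t")
    loo
  })

  res$thermal <- stage("thermal", {
    wpath <- file.path(dd, "weather.csv")
    if (!file.exists(wpath))
      stop_invalid("thermal stage requested but weather file '%s' is missing", wpath)
    weather <- read_weather(wpath)
    spath <- file.path(dd, "stations.csv")
    stations <- if (file.exists(spath)) fread_vc(spath) else
      unique(data.frame(station_id = weather$station_id, latitude = NA, longitude = NA))
    loo <- res$predictability
    spr <- sheet[match(pairs$spring_id, sheet$sample_id), ]
    fal <- sheet[match(pairs$fall_id, sheet$sample_id), ]
    st <- nearest_station(spr, stations)
    sc <- data.frame(locality = pairs$locality, score = loo$score,
                     station_id = st$station_id,
                     spring_date = spr$collection_date,
                     fall_date = fal$collection_date)
    drop_ <- is.na(sc$spring_date) | is.na(sc$fall_date) |
      !(sc$station_id %in% weather$station_id)
    if (any(drop_))
      log_line("thermal: dropped %d population(s) without dates or weather: %s",
               sum(drop_), paste(sc$locality[drop_], collapse = ", "))
    sc <- sc[!drop_, , drop = FALSE]
    tp <- thermal_scan_perm(sc, weather, config$thermal_limits,
                            config$thermal_step, coarse_step = 1,
                            n_perms = config$n_perms_thermal,
                            seed = substream_seed(config$seed, "thermal"))
    out <- cbind(tp$scan$best, p_perm = tp$p)
    write_vc(out, file.path(config$out_dir, "thermal_best.tsv"),
             "thermal-scan", sep = "\t")
    log_line("thermal: best limits (%.1f, %.1f), R2 %.3f, p_perm %.4g",
             out$upper, out$lower, out$r2, out$p_perm)
    list(scores = sc, perm = tp)
  })

  manifest <- list(package = "seasonscan",
                   version = as.character(utils::packageVersion("seasonscan")),
                   config = lapply(unclass(config), function(x)
                     if (inherits(x, "filter_config")) unclass(x) else x))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Summarize pipeline outputs
#'
#' Reads the TSVs a [run_pipeline()] call wrote and produces a compact
#' human-readable summary (plus, when ggplot2 is installed, PDF figures of
#' the enrichment and concordance panels). No statistic is recomputed.
#'
#' @param results_dir a pipeline output directory.
#' @param plots write PDF figures (requires ggplot2).
#' @return character vector of summary lines (also written to
#'   `report.txt`).
#' @export
make_report <- function(results_dir, plots = TRUE) {
  if (!dir.exists(results_dir) || length(dir(results_dir)) == 0)
    stop_invalid("make_report: '%s' is empty or missing", results_dir)
  lines <- c(sprintf("seasonscan report: %s", results_dir))
  grab <- function(f) {
    p <- file.path(results_dir, f)
    if (file.exists(p)) fread_vc(p) else NULL
  }
  enr <- grab("seasonal_enrichment.tsv")
  if (!is.null(enr))
    lines <- c(lines, sprintf("%s enrichment at q=%.3g: %.2fx (p_perm %.4g)",
                              enr$test, enr$q, enr$enrichment, enr$p_perm))
  else lines <- c(lines, "seasonal enrichment: MISSING")
  re <- grab("region_enrichment.tsv")
  if (!is.null(re))
    lines <- c(lines, sprintf("region %s/%s: enrichment %.2f%s", re$chrom,
                              re$region, re$enrichment,
                              ifelse(re$significant %in% TRUE, " *", "")))
  cc <- grab("concordance_curve.tsv")
  if (!is.null(cc))
    lines <- c(lines, sprintf("concordance at q=%.4g: %.3f (n=%d)",
                              cc$q, cc$concordance, cc$n_used))
  ps <- grab("predictability_scores.tsv")
  if (!is.null(ps))
    lines <- c(lines, sprintf("predictability %s: score %+.3f", ps$pair_id,
                              ps$score))
  tb <- grab("thermal_best.tsv")
  if (!is.null(tb))
    lines <- c(lines, sprintf("thermal best limits: upper %.1f C, lower %.1f C, R2 %.3f, p_perm %.4g",
                              tb$upper, tb$lower, tb$r2, tb$p_perm))
  writeLines(lines, file.path(results_dir, "report.txt"))
  if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
    if (!is.null(cc)) {
      g <- ggplot2::ggplot(cc, ggplot2::aes(x = q, y = concordance)) +
        ggplot2::geom_pointrange(ggplot2::aes(ymin = ci_low, ymax = ci_high)) +
        ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
        ggplot2::scale_x_log10() +
        ggplot2::labs(x = "joint quantile", y = "seasonal-clinal concordance")
      ggplot2::ggsave(file.path(results_dir, "concordance.pdf"), g,
                      width = 5, height = 4)
    }
    if (!is.null(ps)) {
      g <- ggplot2::ggplot(ps, ggplot2::aes(x = reorder(pair_id, score), y = score)) +
        ggplot2::geom_col() + ggplot2::coord_flip() +
        ggplot2::labs(x = NULL, y = "predictability score")
      ggplot2::ggsave(file.path(results_dir, "predictability.pdf"), g,
                      width = 5, height = 5)
    }
  }
  lines
}
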