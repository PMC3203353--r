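#' Run the full hot-spot analysis pipeline from a config file
#'
#' Drives the complete analysis the package implements: read inputs, bin
#' and z-score each dataset, call hot-spots by the configured methods
#' (respecting the automatic method-selection rules), compute clustering
#' metrics, pairwise hot-bin conservation, genomic-feature densities, and
#' merge results across shifted partitions. All outputs are plain-text
#' (TSV/BED/JSON) in `out_dir` and are a pure function of the inputs,
#' configuration and seeds.
#'
#' Config keys (YAML): `genome` (path to a chrom-sizes file, or `"hg18"`),
#' `datasets` (name: path map), `bin_size` (default 1e6), `shifts` (default
#' 0), `threshold` (number, or `{reference: <dataset name or path>,
#' percentile: 99.92}`), `methods` (subset of cis/zthreshold/bcp), `bcp`
#' (`iterations`, `burnin`, `p0`, `w0`, `seed`), `cis_rules`
#' (`window`/`min_count` vectors), `tracks` (name: path map),
#' `cancer_genes` (path of gene names, one per line).
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param out_dir Output directory (created if needed); defaults to
#'   `config$out_dir` or `"vishotspot_out"`.
#' @return The output directory path, invisibly; side effect: files written.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- out_dir %||% cfg$out_dir %||% "vishotspot_out"
  # -- validate inputs up front, before any computation
  if (is.null(cfg$datasets) || length(cfg$datasets) == 0)
    abort("config lists no datasets")
  missing <- purrr::keep(cfg$datasets, ~ is.character(.x) && !file.exists(.x))
  if (length(missing))
    abort(paste0("missing VIS file(s): ",
                 paste(unlist(missing), collapse = ", ")))
  genome <- cfg$genome %||% "hg18"
  chrom_sizes <- if (identical(genome, "hg18")) hg18_chrom_sizes()
                 else read_chrom_sizes(genome)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bin_size <- cfg$bin_size %||% 1e6
  shifts <- cfg$shifts %||% 0
  methods <- cfg$methods %||% c("cis", "zthreshold", "bcp")
  bcp_cfg <- cfg$bcp %||% list()
  iterations <- bcp_cfg$iterations %||% 10000
  burnin <- bcp_cfg$burnin %||% 50
  p0 <- bcp_cfg$p0 %||% 0.2
  w0 <- bcp_cfg$w0 %||% 0.2
  seed <- bcp_cfg$seed %||% 1
  rules <- if (is.null(cfg$cis_rules)) cis_rules()
           else cis_rules(cfg$cis_rules$window, cfg$cis_rules$min_count)

  datasets <- purrr::imap(cfg$datasets, function(p, nm)
    if (is.character(p)) read_vis(p, chrom_sizes, name = nm) else
      validate_vis(p, chrom_sizes, name = nm))

  partitions <- purrr::map(shifts, ~ partition_genome(chrom_sizes, bin_size, .x))
  names(partitions) <- paste0("shift", shifts)
  part0 <- partitions[[1]]

  profiles <- purrr::map(datasets, ~ add_zscores(bin_counts(.x, part0)))

  # threshold: fixed value or calibrated from a reference profile
  thr_cfg <- cfg$threshold %||% 422
  threshold <- if (is.numeric(thr_cfg)) {
    threshold_spec(thr_cfg)
  } else {
    ref <- thr_cfg$reference
    ref_prof <- if (ref %in% names(profiles)) profiles[[ref]] else
      add_zscores(bin_counts(read_vis(ref, chrom_sizes), part0))
    get_threshold(ref_prof, thr_cfg$percentile %||% 99.92)
  }

  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  hotbin_sets <- list(); method_used <- character(); all_metrics <- list()
  for (nm in names(datasets)) {
    vis <- datasets[[nm]]; prof <- profiles[[nm]]
    write.table(prof, file.path(out_dir, paste0(nm, "_profile.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    fit <- NULL
    if ("bcp" %in% methods && nrow(vis) > 100) {
      fit <- bcp_fit(prof, iterations, burnin, p0, w0, seed = seed)
      tidy_fit <- tidy(fit)
      write.table(tidy_fit, file.path(out_dir, paste0(nm, "_bcp.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    metrics <- cluster_metrics(prof, fit)
    all_metrics[[nm]] <- dplyr::mutate(metrics, dataset = nm, .before = 1)
    for (m in intersect(methods, c("cis", "zthreshold", "bcp"))) {
      eff <- m
      if (m == "bcp") {
        if (nrow(vis) <= 100) {
          say("[%s] bcp skipped: <= 100 VIS, no rule defined", nm); next
        }
        eff <- select_method(nrow(vis), 1 - fit$p_bar)
        if (eff != "bcp")
          say("[%s] bcp request rerouted to %s (%s)", nm, eff,
              attr(eff, "reason"))
      }
      hs <- switch(eff,
        cis = cis_scan(vis, rules),
        zthreshold = suppressWarnings(refine_hotspots(
          call_hotbins(prof, threshold, "zscore"), vis, part0)),
        bcp = suppressWarnings(refine_hotspots(
          bcp_hotbins(fit, threshold), vis, part0, method = "bcp")))
      if (m == "bcp" && eff != "bcp") hs$method <- paste0("bcp_via_", eff)
      write_hotspots(hs, file.path(out_dir, paste0(nm, "_", m, ".bed")),
                     file.path(out_dir, paste0(nm, "_", m, "_stats.tsv")))
      if (m != "cis") {
        hb <- if (eff == "bcp") bcp_hotbins(fit, threshold)
              else call_hotbins(prof, threshold, "zscore")
        if (m == "bcp" || !("bcp" %in% methods)) {
          hotbin_sets[[nm]] <- hb
          method_used[nm] <- eff
        }
      }
      # shifted partitions + merge (step 7)
      if (length(partitions) > 1 && m != "cis") {
        per_shift <- purrr::map(partitions, function(pt) {
          pr <- add_zscores(bin_counts(vis, pt))
          hb2 <- if (eff == "bcp")
            bcp_hotbins(bcp_fit(pr, iterations, burnin, p0, w0, seed = seed),
                        threshold)
          else call_hotbins(pr, threshold, "zscore")
          suppressWarnings(refine_hotspots(hb2, vis, pt, method = eff))
        })
        merged <- merge_hotspots(per_shift, vis, shifts = shifts)
        write_hotspots(merged,
                       file.path(out_dir, paste0(nm, "_", m, "_merged.bed")),
                       file.path(out_dir, paste0(nm, "_", m, "_merged_stats.tsv")))
      }
    }
  }
  write.table(dplyr::bind_rows(all_metrics),
              file.path(out_dir, "cluster_metrics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(hotbin_sets) >= 2) {
    cons <- conservation_report(hotbin_sets, n = nrow(part0),
                                methods = method_used[names(hotbin_sets)])
    write.table(cons, file.path(out_dir, "conservation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cfg$tracks)) {
    feats <- list()
    for (tnm in names(cfg$tracks)) {
      track <- read_track(cfg$tracks[[tnm]], name = tnm)
      gd <- genome_density_profile(track, part0)
      for (nm in names(datasets)) {
        hs_path <- file.path(out_dir, paste0(nm, "_",
          if ("bcp" %in% methods) "bcp" else methods[1], "_stats.tsv"))
        if (!file.exists(hs_path)) next
        vis <- datasets[[nm]]; prof <- profiles[[nm]]
        # recompute hot-spots for the primary method from persisted inputs
        hb <- hotbin_sets[[nm]]
        if (is.null(hb)) next
        hs <- suppressWarnings(refine_hotspots(hb, vis, part0,
                                               method = method_used[[nm]]))
        if (nrow(hs) == 0) next
        fd <- feature_density(hs, track)
        cmp <- compare_to_genome(fd$feature_density, gd$per_bin$density)
        feats[[paste(nm, tnm, sep = "|")]] <-
          dplyr::mutate(cmp, dataset = nm, track = tnm, .before = 1)
      }
    }
    if (length(feats))
      write.table(dplyr::bind_rows(feats),
                  file.path(out_dir, "feature_comparison.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  meta <- list(
    package = "vishotspot",
    version = as.character(utils::packageVersion("vishotspot")),
    genome = if (identical(genome, "hg18")) "hg18 chr1-22+X+Y" else genome,
    n_bins = nrow(part0), bin_size = bin_size, shifts = shifts,
    methods = methods,
    threshold = unclass(threshold),
    quantile_convention = "type 7 (linear interpolation)",
    bcp = list(iterations = iterations, burnin = burnin, p0 = p0, w0 = w0,
               seed = seed),
    datasets = purrr::map_int(datasets, nrow))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
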