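#' Reporting arithmetic: co-localized percentage
#'
#' Percentage of a peak set carrying a partner within the window, the number
#' quoted alongside nested-set selections (e.g. ~123,000 of ~458,000 peaks
#' is ~27%).
#'
#' @param n_selected Number of peaks in the selected subset.
#' @param n_total Total peaks in the parent set.
#' @return Percentage (0-100).
#' @export
coloc_percent <- function(n_selected, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  100 * n_selected / n_total
}

#' Reporting arithmetic: mean inter-peak interval
#'
#' Genome length divided by the number of peaks — the back-of-envelope mean
#' spacing of a site class (e.g. ~123,000 sites on a 3e9 bp genome are
#' ~24.4 kb apart). Returns `NA` for an empty set instead of dividing by
#' zero.
#'
#' @param genome_length Total genome length in bp (or a [genome_model()]).
#' @param n Number of peaks.
#' @return Mean interval in bp, or `NA` if `n` is 0.
#' @export
mean_peak_interval <- function(genome_length, n) {
  if (inherits(genome_length, "genome_model")) {
    genome_length <- sum(genome_length$length)
  }
  if (n <= 0) return(NA_real_)
  genome_length / n
}

#' Default demonstration pipeline configuration
#'
#' An all-synthetic scenario mirroring the structure of the pre-RC analysis:
#' an anchor peak layer (MCM7-like), a query layer with a 27% co-localized
#' fraction (CDC6-like), nested selection down to a doubly-selected class,
#' a TSS-proximity test, anchor aggregation, and a FAIRE knockdown
#' comparison with factor 0.7 at the nested sites.
#'
#' @param seed Master seed.
#' @return A named list accepted by [run_pipeline()].
#' @export
default_demo_config <- function(seed = 1) {
  list(
    seed = seed,
    genome = list(n_chroms = 3, chrom_length = 2e7),
    params = list(step = 100, window = 1000, d = 500, flank = 5000,
                  agg_flank = 5000, halfwidth = 2000, n_shuffles = 10,
                  pseudocount = 0.5, metric = "edge", mode = "same_chrom",
                  test = "paired_wilcoxon"),
    layers = list(
      list(type = "peaks", label = "MCM7", n_peaks = 2000),
      list(type = "peaks", label = "CDC6", n_peaks = 2000, fraction = 0.27,
           anchor = "MCM7", distinct_anchors = TRUE),
      list(type = "select", a = "CDC6", b = "MCM7"),
      list(type = "peaks", label = "sGRWD1", n_peaks = "match_anchor",
           fraction = 0.27, anchor = "CDC6_w0.5_MCM7",
           distinct_anchors = TRUE),
      list(type = "select", a = "CDC6_w0.5_MCM7", b = "sGRWD1")
    ),
    coloc_tests = list(
      list(a = "CDC6", b = "MCM7"),
      list(a = "CDC6_w0.5_MCM7", b = "sGRWD1")
    ),
    annotation = list(n_genes = 250, length_range = c(2e4, 1e5)),
    tss_test = list(peaks = "CDC6_w0.5_MCM7"),
    aggregate = list(query = "CDC6", anchors = "MCM7"),
    metagene = list(peaks = "CDC6_w0.5_MCM7"),
    faire = list(sites = "CDC6_w0.5_MCM7_w0.5_sGRWD1", n_reads = 1e5,
                 enrichment = 60, knockdown_factor = 0.7)
  )
}

#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates simulate -> select -> test -> profile -> FAIRE-compare behind
#' a single config (an R list or a YAML file path; see
#' [default_demo_config()] for the schema). Every stochastic stage draws its
#' seed deterministically from the master seed and the stage name via
#' [stage_seed()], so two runs with the same config produce byte-identical
#' BED/TSV/JSON outputs (the manifest additionally records wall-clock
#' timings, which differ between runs).
#'
#' Outputs written under `out_dir`: `genome.chrom.sizes`, one BED per peak
#' layer and derived selection, `annotation.tsv`, OverlapReports as JSON,
#' aggregation and metagene profiles as TSV, FAIRE condition tracks as
#' bedGraph, `faire_comparison.json`, `manifest.json`, `summary.txt`.
#'
#' @param config Config list or path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @return An object of class `prerc_run` with the resolved config, the
#'   registry of peak sets, reports, profiles and output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop("config needs a master seed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pr <- config$params
  d <- if (is.null(pr$d)) 500 else pr$d
  timings <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  genome <- tick("genome", {
    if (!is.null(config$genome$chrom_sizes)) {
      read_chrom_sizes(config$genome$chrom_sizes)
    } else {
      make_genome(config$genome$n_chroms, config$genome$chrom_length)
    }
  })
  write_chrom_sizes(genome, file.path(out_dir, "genome.chrom.sizes"))

  sets <- list()
  for (ly in config$layers) {
    if (ly$type == "peaks") {
      anchor <- if (is.null(ly$anchor)) NULL else sets[[ly$anchor]]
      if (!is.null(ly$anchor) && is.null(anchor)) {
        stop("layer '", ly$label, "' anchors to unknown set '", ly$anchor, "'")
      }
      np <- ly$n_peaks
      if (identical(np, "match_anchor")) np <- n_peaks(anchor)
      sets[[ly$label]] <- tick(paste0("peaks:", ly$label), {
        if (!is.null(ly$bed)) {
          read_bed(ly$bed, genome, label = ly$label)
        } else {
          simulate_peaks(
            genome, n_peaks = np,
            length_range = if (is.null(ly$length_range)) c(300, 1500)
                           else unlist(ly$length_range),
            fraction = ly$fraction,
            window = if (is.null(ly$window)) d else ly$window,
            anchor = anchor,
            min_gap = if (is.null(ly$min_gap)) 0 else ly$min_gap,
            distinct_anchors = isTRUE(ly$distinct_anchors),
            seed = stage_seed(config$seed, paste0("peaks:", ly$label)),
            label = ly$label)
        }
      })
    } else if (ly$type == "select") {
      dd <- if (is.null(ly$d)) d else ly$d
      sel <- tick(paste0("select:", ly$a, ":", ly$b), {
        select_within(sets[[ly$a]], sets[[ly$b]], d = dd,
                      metric = if (is.null(pr$metric)) "edge" else pr$metric)
      })
      sets[[sel$selected$label]] <- sel$selected
      sets[[sel$complement$label]] <- sel$complement
    } else {
      stop("unknown layer type: ", ly$type)
    }
  }
  for (nm in names(sets)) {
    write_bed(sets[[nm]], file.path(out_dir, paste0(nm, ".bed")))
  }

  reports <- list()
  for (ct in config$coloc_tests) {
    nm <- paste0("coloc_", ct$a, "_vs_", ct$b)
    reports[[nm]] <- tick(nm, {
      coloc_test(sets[[ct$a]], sets[[ct$b]],
                 d = if (is.null(ct$d)) d else ct$d,
                 n_shuffles = if (is.null(pr$n_shuffles)) 10 else pr$n_shuffles,
                 seed = stage_seed(config$seed, nm),
                 metric = if (is.null(pr$metric)) "edge" else pr$metric,
                 mode = if (is.null(pr$mode)) "same_chrom" else pr$mode)
    })
    write_report_json(reports[[nm]], file.path(out_dir, paste0(nm, ".json")))
  }

  annotation <- NULL
  if (!is.null(config$annotation)) {
    annotation <- tick("annotation", {
      if (!is.null(config$annotation$path)) {
        read_annotation(config$annotation$path, genome)
      } else {
        simulate_annotation(
          genome, config$annotation$n_genes,
          length_range = if (is.null(config$annotation$length_range))
            c(1e4, 1e5) else unlist(config$annotation$length_range),
          seed = stage_seed(config$seed, "annotation"))
      }
    })
    write_annotation(annotation, file.path(out_dir, "annotation.tsv"))
  }

  if (!is.null(config$tss_test) && !is.null(annotation)) {
    nm <- paste0("tss_", config$tss_test$peaks)
    reports[[nm]] <- tick(nm, {
      tss_proximity_test(sets[[config$tss_test$peaks]], annotation, d = d,
                         n_shuffles = if (is.null(pr$n_shuffles)) 10
                                      else pr$n_shuffles,
                         seed = stage_seed(config$seed, nm))
    })
    write_report_json(reports[[nm]], file.path(out_dir, paste0(nm, ".json")))
  }

  profiles <- list()
  if (!is.null(config$aggregate)) {
    profiles$aggregation <- tick("aggregate", {
      aggregate_peak_density(
        sets[[config$aggregate$query]], sets[[config$aggregate$anchors]],
        flank = if (is.null(pr$agg_flank)) 5000 else pr$agg_flank,
        step = if (is.null(pr$step)) 100 else pr$step,
        seed = stage_seed(config$seed, "aggregate"))
    })
    write_profile_tsv(profiles$aggregation,
                      file.path(out_dir, "aggregation_profile.tsv"))
  }

  if (!is.null(config$metagene) && !is.null(annotation)) {
    profiles$metagene <- tick("metagene", {
      metagene_frequency(sets[[config$metagene$peaks]], annotation,
                         flank = if (is.null(pr$flank)) 5000 else pr$flank)
    })
    mg <- profiles$metagene
    con <- file(file.path(out_dir, "metagene_profile.tsv"), "w")
    writeLines("bin\tsection\tmean_density\tcount", con)
    writeLines(sprintf("%d\t%s\t%.6g\t%d", seq_along(mg$value), mg$section,
                       mg$value, as.integer(mg$counts)), con)
    close(con)
  }

  faire <- NULL
  if (!is.null(config$faire)) {
    fc <- config$faire
    faire <- tick("faire", {
      sites <- sets[[fc$sites]]
      nr <- if (is.null(fc$n_reads)) 1e5 else fc$n_reads
      enr <- if (is.null(fc$enrichment)) 60 else fc$enrichment
      g <- if (is.null(fc$knockdown_factor)) 0.7 else fc$knockdown_factor
      ctrl <- simulate_reads(genome, sites, n_reads = nr, enrichment = enr,
                             effect = 1, paired_input = TRUE,
                             seed = stage_seed(config$seed, "faire:ctrl"))
      kd <- simulate_reads(genome, sites, n_reads = nr, enrichment = enr,
                           effect = g, paired_input = TRUE,
                           seed = stage_seed(config$seed, "faire:kd"))
      step <- if (is.null(pr$step)) 100 else pr$step
      window <- if (is.null(pr$window)) 1000 else pr$window
      mk <- function(rs) {
        subtract_input(normalize_rpm(bin_reads(rs$sample, genome, step, window)),
                       normalize_rpm(bin_reads(rs$input, genome, step, window)))
      }
      t_ctrl <- mk(ctrl)
      t_kd <- mk(kd)
      write_bedgraph(t_ctrl, file.path(out_dir, "faire_ctrl.bedgraph"),
                     suppress_zero = TRUE)
      write_bedgraph(t_kd, file.path(out_dir, "faire_kd.bedgraph"),
                     suppress_zero = TRUE)
      prof <- aggregate_signal(t_ctrl, sites,
                               flank = if (is.null(pr$halfwidth)) 2000
                                       else pr$halfwidth)
      write_profile_tsv(prof, file.path(out_dir, "faire_ctrl_profile.tsv"))
      cmp <- faire_compare(t_ctrl, t_kd, sites,
                           halfwidth = if (is.null(pr$halfwidth)) 2000
                                       else pr$halfwidth,
                           test = if (is.null(pr$test)) "paired_wilcoxon"
                                  else pr$test)
      jsonlite::write_json(
        list(halfwidth = cmp$halfwidth, anchors = cmp$anchors_used,
             mean_ctrl = cmp$mean_1, mean_kd = cmp$mean_2,
             percent_change = cmp$percent_change, p_value = cmp$p_value,
             test = cmp$test_name),
        file.path(out_dir, "faire_comparison.json"),
        auto_unbox = TRUE, digits = NA)
      cmp
    })
  }

  run <- structure(list(config = config, out_dir = out_dir, genome = genome,
                        sets = sets, reports = reports, profiles = profiles,
                        faire = faire, annotation = annotation,
                        timings = timings),
                   class = "prerc_run")

  files <- setdiff(list.files(out_dir), c("manifest.json", "summary.txt"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("prercoloc")),
    config = config,
    files = as.list(tools::md5sum(file.path(out_dir, sort(files)))),
    timings = timings)
  names(manifest$files) <- sort(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(summarize_run(run), file.path(out_dir, "summary.txt"))
  run
}

write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.prerc_run <- function(x, ...) {
  cat("pipeline run ->", x$out_dir, "\n")
  cat(summarize_run(x), sep = "\n")
  invisible(x)
}

#' Human-readable summary of a pipeline run
#'
#' Set sizes, co-localized fractions, mean inter-peak intervals (genome
#' length / set size), chi-square p-values and the FAIRE percent change.
#'
#' @param run A `prerc_run` from [run_pipeline()].
#' @return Character vector of report lines.
#' @export
summarize_run <- function(run) {
  stopifnot(inherits(run, "prerc_run"))
  G <- genome_length(run$genome)
  out <- c(sprintf("genome: %d chromosome(s), %.3g bp", length(run$genome$chrom), G),
           "", "peak sets:")
  for (nm in names(run$sets)) {
    n <- n_peaks(run$sets[[nm]])
    mi <- mean_peak_interval(G, n)
    out <- c(out, sprintf("  %-40s %6d peaks  mean interval %s", nm, n,
                          if (is.na(mi)) "n/a" else fmt_kb(mi)))
  }
  if (length(run$reports)) {
    out <- c(out, "", "co-localization tests:")
    for (nm in names(run$reports)) {
      r <- run$reports[[nm]]
      out <- c(out, sprintf(
        "  %s vs %s (d=%g bp): %.1f%% observed vs %.1f%% shuffled, chi2=%.1f, p=%.3g",
        r$label_A, r$label_B, r$d, 100 * r$fraction_observed,
        100 * r$fraction_null, r$chi2, r$p_value))
    }
  }
  if (!is.null(run$faire)) {
    f <- run$faire
    out <- c(out, "", sprintf(
      "FAIRE comparison (+/- %d bp, %d sites): %.1f%% change, p=%.3g (%s)",
      f$halfwidth, f$anchors_used, f$percent_change, f$p_value, f$test_name))
  }
  out
}
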