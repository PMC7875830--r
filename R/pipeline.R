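#' Run the full introgression-detection pipeline
#'
#' Orchestrates simulate (or load) -> filter -> NJ clustering -> admixture
#' -> D-statistics -> contamination check as one reproducible run, writing
#' every stage's table into `out_dir` together with a human-readable
#' summary. Stage seeds all derive from the global seed, so a rerun with
#' the same configuration is byte-identical.
#'
#' @param config a named list, or path to a YAML file with the same
#'   structure. Top-level blocks:
#'   \describe{
#'     \item{`simulate`}{arguments for [sim_config()] (exclusive with
#'       `input`).}
#'     \item{`input`}{list with `vcf` (path) and optionally `populations`
#'       (2-column TSV: sample, population) and `sam` (vector of SAM/BAM
#'       paths for the contamination stage).}
#'     \item{`filter`}{`biallelic` (default TRUE), `min_qual` (default
#'       NULL: skip), `drop_invariant` (default TRUE).}
#'     \item{`admixture`}{arguments for [admix_config()]; samples of the
#'       `outgroup` population are excluded from this stage.}
#'     \item{`dstat`}{`outgroup`, `trios` (list of c(p1, p2, test)),
#'       `n_blocks`. For simulated data sensible defaults are derived from
#'       the truth (donor species vs non-admixed conspecifics vs focal).}
#'     \item{`contam`}{for simulated runs: arguments for [simulate_sam()]
#'       per library (`n_libraries`, `n_reads`, `read_len`,
#'       `per_base_mismatch`, `spike` list); omit to skip.}
#'     \item{`seed`}{global seed (default 1).}
#'   }
#' @param out_dir output directory (created if needed).
#' @return list of class `run_report` with one element per stage (skipped
#'   stages are the string `"skipped"`) and a `provenance` block.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  report <- list()
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)

  # --- genotypes: simulate or load -------------------------------------
  if (!is.null(config$simulate) && !is.null(config$input$vcf)) {
    stop("config must supply exactly one of 'simulate' and 'input'")
  }
  truth <- NULL
  if (!is.null(config$simulate)) {
    sc <- do.call(sim_config, c(config$simulate, list(seed = seed)))
    sim <- simulate_study(sc)
    gm <- sim$matrix
    truth <- sim$truth
    write_sim_vcf(gm, file.path(out_dir, "simulated.vcf"))
    write_truth(truth, file.path(out_dir, "truth.tsv"))
    report$simulate <- list(n_loci = n_loci(gm), n_samples = n_samples(gm),
                            q_true = attr(truth, "q_true"),
                            focal = sc$recipient_sample)
    logf("simulate: %d loci, %d samples, q_true=%.4f", n_loci(gm),
         n_samples(gm), attr(truth, "q_true"))
  } else if (!is.null(config$input$vcf)) {
    gm <- read_vcf(config$input$vcf)
    if (!is.null(config$input$populations)) {
      pop <- utils::read.table(config$input$populations, sep = "\t",
                               header = FALSE, stringsAsFactors = FALSE)
      gm$populations <- stats::setNames(pop[[2]], pop[[1]])[sample_ids(gm)]
    }
    sc <- NULL
    report$simulate <- "skipped"
    logf("input: %s (%d loci, %d samples)", config$input$vcf, n_loci(gm),
         n_samples(gm))
  } else {
    stop("config must supply a 'simulate' block or an 'input' block")
  }

  # --- filtering -------------------------------------------------------
  fc <- config$filter
  if (is.null(fc$biallelic) || isTRUE(fc$biallelic)) {
    gm <- filter_biallelic(gm)
  }
  if (!is.null(fc$min_qual)) gm <- filter_quality(gm, fc$min_qual)
  if (is.null(fc$drop_invariant) || isTRUE(fc$drop_invariant)) {
    gm <- drop_invariant(gm)
  }
  write_filter_report(gm, file.path(out_dir, "filter_report.tsv"))
  report$filter <- filter_log(gm)
  logf("filter: %d loci retained", n_loci(gm))
  if (n_loci(gm) == 0) stop("pipeline aborted at stage 'filter': no loci left")

  # --- NJ clustering ---------------------------------------------------
  report$nj <- tryCatch({
    d <- euclidean_distances(gm)
    tree <- neighbor_joining(d)
    write_dist_tsv(d, file.path(out_dir, "distances.tsv"))
    write_newick(tree, file.path(out_dir, "tree.nwk"))
    logf("nj: tree with %d tips", length(tree$tip.label))
    list(newick = readLines(file.path(out_dir, "tree.nwk")), tree = tree)
  }, error = function(e) stop("pipeline aborted at stage 'nj': ",
                              conditionMessage(e)))

  # --- admixture -------------------------------------------------------
  ac_args <- config$admixture
  if (is.null(ac_args)) ac_args <- list()
  ac_args$seed <- seed + 1000L
  ac <- do.call(admix_config, ac_args)
  ingroup <- gm
  if (!is.null(gm$populations) && any(gm$populations == "outgroup")) {
    keep <- sample_ids(gm)[gm$populations != "outgroup"]
    ingroup$dosage <- gm$dosage[keep, , drop = FALSE]
    if (!is.null(gm$gt)) ingroup$gt <- gm$gt[keep, , drop = FALSE]
    ingroup$populations <- gm$populations[keep]
    ingroup <- drop_invariant(ingroup)
  }
  admix <- run_admixture(ingroup, ac)
  write_q_table(admix, file.path(out_dir, "admixture_q.tsv"),
                populations = ingroup$populations)
  report$admixture <- admix
  logf("admixture: K=%d, %d draws", ac$K, admix$n_draws)

  # --- D-statistics ----------------------------------------------------
  dc <- config$dstat
  if (is.null(dc) && !is.null(truth) && !is.null(sc) &&
      !is.na(sc$recipient_sample)) {
    donor_pop <- sc$donor
    recip_pop <- setdiff(c("speciesA", "speciesB"), donor_pop)
    controls <- setdiff(sc$sample_ids[sc$populations == recip_pop],
                        sc$recipient_sample)
    dc <- list(outgroup = "outgroup",
               trios = lapply(controls, function(ctrl) {
                 c(donor_pop, ctrl, sc$recipient_sample)
               }),
               n_blocks = 50)
  }
  if (!is.null(dc)) {
    nb <- if (is.null(dc$n_blocks)) 50 else dc$n_blocks
    dtab <- qp_dstat_table(gm, dc$outgroup, dc$trios, n_blocks = nb)
    utils::write.table(dtab, file.path(out_dir, "dstat.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$dstat <- dtab
    logf("dstat: %d trios", nrow(dtab))
  } else {
    report$dstat <- "skipped"
  }

  # --- contamination check --------------------------------------------
  cc <- config$contam
  if (!is.null(cc) || !is.null(config$input$sam)) {
    stats_list <- if (!is.null(config$input$sam)) {
      lapply(config$input$sam, mismatch_rate)
    } else {
      n_lib <- if (is.null(cc$n_libraries)) 8L else cc$n_libraries
      spike <- cc$spike
      lapply(seq_len(n_lib), function(i) {
        spiked <- !is.null(spike) && i == spike$library
        sim <- simulate_sam(
          n_reads = if (is.null(cc$n_reads)) 1000L else cc$n_reads,
          read_len = if (is.null(cc$read_len)) 100L else cc$read_len,
          per_base_mismatch = if (is.null(cc$per_base_mismatch)) 0.01 else
            cc$per_base_mismatch,
          contaminant_fraction = if (spiked) spike$fraction else 0,
          contaminant_divergence = if (spiked) spike$divergence else 0,
          seed = seed + 2000L + i)
        sam_path <- file.path(out_dir, sprintf("library%02d.sam", i))
        write_sam(sim, sam_path)
        mismatch_rate(sam_path, sample_id = sprintf("library%02d", i))
      })
    }
    ctab <- compare_samples(stats_list)
    utils::write.table(ctab, file.path(out_dir, "contamination.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$contam <- ctab
    logf("contam: %d libraries, %d flagged", nrow(ctab), sum(ctab$flagged))
  } else {
    report$contam <- "skipped"
  }

  # --- summary ---------------------------------------------------------
  report$provenance <- list(seed = seed, timestamp = NA,
                            package_version =
                              as.character(utils::packageVersion("introkit")))
  write_run_summary(report, file.path(out_dir, "summary.txt"))
  class(report) <- "run_report"
  report
}

write_run_summary <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("introgression pipeline run (seed %d)", report$provenance$seed)
  if (!identical(report$simulate, "skipped")) {
    w("simulated data: %d loci, %d samples, realized introgressed fraction %.4f (focal %s)",
      report$simulate$n_loci, report$simulate$n_samples,
      report$simulate$q_true, report$simulate$focal)
  }
  w("loci after filtering: %d", utils::tail(report$filter$n_out, 1))
  if (!identical(report$nj, "skipped")) {
    w("NJ tree: %s", report$nj$newick[1])
  }
  if (!identical(report$admixture, "skipped")) {
    q <- report$admixture$Q_mean
    for (i in seq_len(nrow(q))) {
      w("ancestry %s: %s", rownames(q)[i],
        paste(sprintf("%.3f", q[i, ]), collapse = " / "))
    }
  }
  if (!identical(report$dstat, "skipped")) {
    d <- report$dstat
    for (i in seq_len(nrow(d))) {
      w("D(%s; %s, %s, %s) = %.4f  Z = %.2f", d$outgroup[i], d$pop1[i],
        d$pop2[i], d$pop3[i], d$D[i], d$Z[i])
    }
  }
  if (!identical(report$contam, "skipped")) {
    c <- report$contam
    w("mismatch rates: %s",
      paste(sprintf("%s=%.4f%s", c$sample_id, c$error_rate,
                    ifelse(c$flagged, "*", "")), collapse = " "))
  }
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report with stages:",
      paste(setdiff(names(x), "provenance"), collapse = ", "), "\n")
  invisible(x)
}
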