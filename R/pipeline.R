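# End-to-end orchestration: one call reproduces every deliverable of the
# matrilineal analysis (diversity report, haplogroup frequencies, novel
# matriline report, diversity profile, NJ tree, haplotype network,
# haplotype representatives, run manifest).

#' Assemble a pipeline run configuration
#'
#' @param fasta,breeds paths to the aligned FASTA and breed TSV; leave
#'   NULL (with `cohort` set) to run on an in-memory synthetic cohort.
#' @param reference path to a single-record FASTA holding the reference
#'   backbone, or a reference sequence string; NULL uses the cohort's.
#' @param cohort optional [generate_cohort()] result used instead of
#'   files.
#' @param motif_table a [motif_table()]; NULL uses the packaged default.
#' @param out_dir output directory.
#' @param site_policy `"complete"` or `"pairwise"`.
#' @param window_size,step diversity-scan parameters (np).
#' @param epsilon median-joining relaxation.
#' @param bootstrap_reps NJ bootstrap replicates.
#' @param seed integer seed for all stochastic stages.
#' @param overwrite allow writing into a non-empty `out_dir`.
#' @return list of class `run_config`.
#' @export
run_config <- function(fasta = NULL, breeds = NULL, reference = NULL,
                       cohort = NULL, motif_table = NULL,
                       out_dir = "mitohap-run", site_policy = "complete",
                       window_size = 200L, step = 25L, epsilon = 0,
                       bootstrap_reps = 1000L, seed = 1L,
                       overwrite = FALSE) {
  if (is.null(cohort) && is.null(fasta)) {
    stop("either input files (fasta) or a cohort must be given")
  }
  structure(
    list(fasta = fasta, breeds = breeds, reference = reference,
         cohort = cohort, motif_table = motif_table, out_dir = out_dir,
         site_policy = site_policy, window_size = as.integer(window_size),
         step = as.integer(step), epsilon = epsilon,
         bootstrap_reps = as.integer(bootstrap_reps),
         seed = as.integer(seed), overwrite = overwrite),
    class = "run_config")
}

load_run_inputs <- function(cfg) {
  if (!is.null(cfg$cohort)) {
    aln <- cfg$cohort$alignment
    ref <- aln$ref_row
  } else {
    ref <- NULL
    if (!is.null(cfg$reference)) {
      ref <- if (file.exists(cfg$reference)) {
        as.character(Biostrings::readBStringSet(cfg$reference)[[1L]])
      } else cfg$reference
    }
    aln <- read_alignment(cfg$fasta, cfg$breeds, ref_seq = ref)
    if (!is.null(ref)) ref <- aln$ref_row
  }
  table <- if (is.null(cfg$motif_table)) {
    default_motif_table(if (!is.null(ref)) sum(ref != "-") else
      aln$aligned_length)
  } else cfg$motif_table
  list(aln = aln, ref = ref, table = table)
}

#' Validate pipeline inputs without running the analysis
#'
#' Dry-run check of file formats, coordinate ranges and motif-table
#' consistency.
#'
#' @param cfg a [run_config()].
#' @return data.frame of diagnostics with columns `level` (`"error"` /
#'   `"warning"` / `"ok"`) and `message`.
#' @export
validate_inputs <- function(cfg) {
  diags <- list()
  note <- function(level, msg) {
    diags[[length(diags) + 1L]] <<- data.frame(
      level = level, message = msg, stringsAsFactors = FALSE)
  }
  if (is.null(cfg$cohort)) {
    for (f in c(fasta = cfg$fasta, breeds = cfg$breeds)) {
      if (!is.null(f) && !file.exists(f)) note("error", paste("missing file:", f))
    }
    if (is.null(cfg$breeds)) note("warning", "no breed map: all samples 'unknown'")
  }
  inp <- tryCatch(load_run_inputs(cfg), error = function(e) {
    note("error", conditionMessage(e))
    NULL
  })
  if (!is.null(inp)) {
    aln <- inp$aln
    note("ok", sprintf("alignment: %d samples x %d columns",
                       nrow(aln$seq), aln$aligned_length))
    max_pos <- max(inp$table$position, na.rm = TRUE)
    frame_len <- if (!is.null(inp$ref)) sum(inp$ref != "-") else
      aln$aligned_length
    if (max_pos > frame_len) {
      note("error", sprintf(
        "motif position %d beyond reference frame length %d",
        max_pos, frame_len))
    } else {
      note("ok", "motif table consistent with reference frame")
    }
    unk <- sum(aln$breed_map == "unknown")
    if (unk > 0L) {
      note("warning", sprintf("%d sample(s) missing from breed map", unk))
    }
    if (is.null(inp$ref)) {
      note("warning", "no reference sequence: haplogroup stage will be skipped")
    }
  }
  out <- do.call(rbind, diags)
  rownames(out) <- NULL
  out
}

#' Run the full matrilineal-diversity pipeline
#'
#' Stages: site indexing, haplotype collapsing, diversity statistics and
#' per-breed report, sliding-window diversity scan, motif haplogroup
#' classification with frequency and novel-matriline reports, NJ tree
#' with bootstrap supports, and the median-joining network. All outputs
#' plus a JSON manifest (input checksums, configuration, package
#' version) are written under `cfg$out_dir`.
#'
#' @param cfg a [run_config()].
#' @return invisible list with every in-memory result (`alignment`,
#'   `site_index`, `haplotypes`, `stats`, `report`, `profile`, `calls`,
#'   `frequencies`, `novel`, `tree`, `network`, `files`).
#' @export
run_pipeline <- function(cfg) {
  diags <- validate_inputs(cfg)
  if (any(diags$level == "error")) {
    stop("input validation failed:\n  ",
         paste(diags$message[diags$level == "error"], collapse = "\n  "))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  existing <- list.files(cfg$out_dir)
  if (length(existing) && !cfg$overwrite) {
    stop("output dir ", cfg$out_dir, " is not empty; set overwrite = TRUE")
  }
  inp <- load_run_inputs(cfg)
  aln <- inp$aln
  idx <- build_site_index(aln, cfg$site_policy)
  h <- collapse_haplotypes(aln, idx)
  stats <- diversity_stats(aln, idx)
  profile <- diversity_scan(aln, idx, cfg$window_size, cfg$step)

  calls <- NULL; freqs <- NULL; novel <- NULL
  if (!is.null(inp$ref)) {
    calls <- classify_cohort(aln, inp$table)
    freqs <- haplogroup_frequencies(calls)
    novel <- detect_novel(calls)
  }
  report <- breed_diversity_report(aln, calls, policy = cfg$site_policy)

  boot <- if (nrow(h$seqs) >= 3L) {
    bootstrap_supports(h, n_reps = cfg$bootstrap_reps, seed = cfg$seed)
  } else {
    warning("fewer than 3 haplotypes: NJ tree skipped")
    NULL
  }
  net <- median_joining(h, epsilon = cfg$epsilon)

  files <- c(report = file.path(cfg$out_dir, "diversity_report.tsv"),
             profile = file.path(cfg$out_dir, "diversity_profile.tsv"),
             tree = file.path(cfg$out_dir, "nj_tree.nwk"),
             network_nodes = file.path(cfg$out_dir, "network_nodes.tsv"),
             network_edges = file.path(cfg$out_dir, "network_edges.tsv"),
             haplotypes = file.path(cfg$out_dir, "haplotypes.fasta"))
  write_tsv(report, files[["report"]])
  write_tsv(as.data.frame(profile), files[["profile"]])
  if (!is.null(boot)) write_tree_newick(boot$tree, files[["tree"]])
  else files <- files[names(files) != "tree"]
  write_network(net, files[["network_nodes"]], files[["network_edges"]])
  write_haplotypes_fasta(h, aln, files[["haplotypes"]])
  if (!is.null(calls)) {
    files <- c(files,
               calls = file.path(cfg$out_dir, "haplogroup_calls.tsv"),
               frequencies = file.path(cfg$out_dir,
                                       "haplogroup_frequencies.tsv"),
               novel = file.path(cfg$out_dir, "novel_matrilines.tsv"))
    write_tsv(calls, files[["calls"]])
    write_tsv(freqs, files[["frequencies"]])
    write_tsv(novel, files[["novel"]])
  }

  manifest <- list(
    package = "mitohap",
    version = as.character(utils::packageVersion("mitohap")),
    seed = cfg$seed,
    site_policy = cfg$site_policy,
    window_size = cfg$window_size, step = cfg$step,
    epsilon = cfg$epsilon, bootstrap_reps = cfg$bootstrap_reps,
    n_samples = nrow(aln$seq), aligned_length = aln$aligned_length,
    usable_sites = length(idx$usable),
    inputs = if (!is.null(cfg$fasta)) {
      as.list(tools::md5sum(c(cfg$fasta, cfg$breeds)))
    } else "in-memory synthetic cohort",
    outputs = as.list(unname(files)))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  files <- c(files, manifest = manifest_path)

  invisible(list(alignment = aln, site_index = idx, haplotypes = h,
                 stats = stats, report = report, profile = profile,
                 calls = calls, frequencies = freqs, novel = novel,
                 tree = boot, network = net, files = files))
}
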