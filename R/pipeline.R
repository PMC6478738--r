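# Pipeline plumbing: chains simulate -> call -> phase -> filter ->
# evaluate, with one global seed, per-stage file outputs and a
# machine-readable summary.

#' Simulate a diploid data set to disk
#'
#' Writes reference FASTA, haplotype FASTAs, truth VCF, reads FASTQ and
#' truth SAM into `out_dir`.
#'
#' @param config a [sim_config()]
#' @param out_dir output directory (created if missing)
#' @return list with the file paths and the in-memory `sim`/`reads`
#' @export
run_simulate <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_diploid(config)
  reads <- simulate_reads(sim, config)
  paths <- list(
    reference = file.path(out_dir, "reference.fa"),
    hap1 = file.path(out_dir, "hap1.fa"),
    hap2 = file.path(out_dir, "hap2.fa"),
    truth_vcf = file.path(out_dir, "truth.vcf"),
    sam = file.path(out_dir, "reads.sam"),
    fastq = file.path(out_dir, "reads.fastq"))
  write_fasta(sim$reference, paths$reference)
  write_fasta(sim$hap1, paths$hap1)
  write_fasta(sim$hap2, paths$hap2)
  rl <- setNames(config$ref_length, config$contig)
  truth <- sim$truth
  truth$qual <- NA_real_
  write_phased_vcf(truth, paths$truth_vcf, ref_lengths = rl)
  write_sam(reads, rl, paths$sam, fastq_path = paths$fastq)
  c(paths, list(sim = sim, reads = reads))
}

#' Run the full pipeline on one simulated data set
#'
#' simulate -> call -> phase (heterozygous calls) -> annotate + filter
#' (both policies) -> evaluate against the truth, returning one
#' consolidated report.  Deterministic given `config$seed`.
#'
#' @param config a [sim_config()]
#' @param out_dir optional output directory; when given, per-stage files
#'   and a JSON summary are written there
#' @param policy a [filter_policy()]; both the `"qual"` and `"phasing"`
#'   variants of it are evaluated
#' @param model a [genotype_model()]
#' @param em an [em_config()]; its seed is overridden by `config$seed`
#' @return list: `calls` (annotated), `phase`, `filtered` (per policy),
#'   `classification` (per policy and unfiltered), `switch_error`,
#'   `config`
#' @export
run_end_to_end <- function(config = sim_config(), out_dir = NULL,
                           policy = filter_policy(),
                           model = genotype_model(),
                           em = em_config()) {
  tmp_dir <- out_dir %||% tempfile("pipeline")
  files <- run_simulate(config, tmp_dir)
  sim <- files$sim

  calls <- call_variants(files$sam, sim$reference, model)

  # phase the heterozygous calls that survive the QUAL threshold: the
  # post-phasing policy applies the phasing metrics on top of a fixed
  # QUAL cut, so only those sites need (or deserve) phase estimates
  aln <- parse_alignments(files$sam)
  hets <- calls[calls$genotype == "het" &
                  calls$qual >= policy$qual_threshold, , drop = FALSE]
  phase <- NULL
  calls$pe <- calls$theta1 <- calls$theta2 <- NA_real_
  calls$phase_set <- calls$hap_of_alt <- NA_integer_
  calls$sb1 <- calls$sb2 <- NA_integer_
  if (nrow(hets) >= 1) {
    obs <- extract_observations(aln, hets)
    em$seed <- config$seed
    phase <- phase_reads(obs, nrow(hets), em)
    hets_phased <- cbind(hets[, c("chrom", "pos")], phase$sites)
    mi <- match(paste(calls$chrom, calls$pos),
                paste(hets_phased$chrom, hets_phased$pos))
    for (col in c("pe", "theta1", "theta2", "phase_set", "hap_of_alt",
                  "sb1", "sb2"))
      calls[[col]][!is.na(mi)] <- hets_phased[[col]][mi[!is.na(mi)]]
  }

  calls <- annotate_calls(calls, sim$reference, policy = policy)

  pol_qual <- filter_policy("qual", qual_threshold = policy$qual_threshold,
                            coverage_floor = policy$coverage_floor,
                            del_ceiling = policy$del_ceiling,
                            homopolymer_len = policy$homopolymer_len,
                            strand_phred = policy$strand_phred,
                            pe_threshold = policy$pe_threshold)
  filtered <- list(qual = apply_policy(calls, pol_qual))
  if (!is.null(phase)) {
    pol_ph <- pol_qual; pol_ph$name <- "phasing"
    filtered$phasing <- apply_policy(calls, pol_ph)
  }

  truth <- sim$truth
  classification <- c(
    list(unfiltered = classify_calls(calls, truth)),
    lapply(filtered, function(f) classify_calls(f$calls, truth)))

  sw <- NULL
  if (!is.null(phase)) {
    phased_calls <- calls[!is.na(calls$hap_of_alt), , drop = FALSE]
    sw <- switch_error_rate(phased_calls, truth, mode = "all")
  }

  report <- list(calls = calls, phase = phase, filtered = filtered,
                 classification = classification, switch_error = sw,
                 files = files[c("reference", "truth_vcf", "sam", "fastq")],
                 config = config)
  if (!is.null(out_dir)) {
    write_phased_vcf(calls[, setdiff(names(calls),
                                     c("theta1", "theta2"))],
                     file.path(out_dir, "calls.vcf"),
                     ref_lengths = setNames(config$ref_length, config$contig))
    summary <- list(
      n_calls = nrow(calls),
      n_pass = vapply(filtered, function(f) nrow(f$calls), numeric(1)),
      removals = lapply(filtered, `[[`, "counts"),
      classification = lapply(classification, function(x)
        x[c("tp", "fp", "fn", "fdr", "fnr", "f1")]),
      switch_error = sw,
      seed = config$seed)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    mt <- calls[calls$genotype == "het",
                c("chrom", "pos", "phase_set", "theta1", "theta2", "pe",
                  "sb1", "sb2")]
    utils::write.table(mt, file.path(out_dir, "phase_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' Evaluate a call VCF against a truth VCF
#'
#' @param calls_vcf,truth_vcf VCF paths (biallelic SNVs)
#' @param region optional data.frame (`chrom`, `start`, `end`)
#' @return list with the [classify_calls()] result and, when both files
#'   carry phased genotypes, the all-pairs switch error
#' @export
run_evaluate <- function(calls_vcf, truth_vcf, region = NULL) {
  calls <- read_vcf(calls_vcf)
  truth <- read_vcf(truth_vcf)
  cls <- classify_calls(calls, truth, region)
  sw <- NULL
  if (any(!is.na(calls$hap_of_alt)) && any(!is.na(truth$hap_of_alt)))
    sw <- switch_error_rate(calls[!is.na(calls$hap_of_alt), ], truth)
  list(classification = cls, switch_error = sw)
}

#' Scaled simulation benchmark: tune, run, evaluate
#'
#' Reproduces the simulation-study protocol at desk scale: the
#' contamination parameter is first selected by best F1 on a small
#' tuning simulation (a held-out seed, mirroring the derive-on-one-
#' chromosome / apply-genome-wide split), then the full pipeline runs on
#' the main simulation and is scored against its truth.
#'
#' @param seed global seed; the tuning simulation uses `seed + 1000`
#' @param ref_length main simulation reference length (default 0.5 Mb)
#' @param depth_per_haplotype per-haplotype depth (default 40, i.e. 80x
#'   total)
#' @param tune_length tuning simulation reference length
#' @param tune select the contamination parameter on the tuning run
#'   (otherwise the clinical default 0.7/0.1 is used)
#' @return list: `model` (the genotype model used), `tuning` (grid
#'   table or NULL), `classification`, `switch_error`, `n_truth`
#' @export
simulation_benchmark <- function(seed, ref_length = 5e5,
                                 depth_per_haplotype = 40,
                                 tune_length = 15e4, tune = TRUE) {
  model <- genotype_model()
  tuning <- NULL
  if (tune) {
    cfg_t <- sim_config(ref_length = tune_length,
                        depth_per_haplotype = depth_per_haplotype,
                        seed = seed + 1000L)
    ft <- run_simulate(cfg_t, tempfile("tune"))
    tuned <- tune_contamination(ft$sam, ft$sim$reference, ft$sim$truth)
    model <- tuned$model
    tuning <- tuned$table
  }
  cfg <- sim_config(ref_length = ref_length,
                    depth_per_haplotype = depth_per_haplotype, seed = seed)
  rep <- run_end_to_end(cfg, model = model)
  list(model = model, tuning = tuning,
       classification = rep$classification,
       switch_error = rep$switch_error,
       n_truth = rep$classification$unfiltered$tp +
         rep$classification$unfiltered$fn)
}
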