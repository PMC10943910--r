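#' Run the full ACP-derivation pipeline
#'
#' Orchestrates every stage in order: simulate (or load) the labelled
#' training sets, featurize, select discriminative features, fit the
#' classifier, simulate (or load) reads, mine ranked candidates,
#' characterize the top candidate, scan its antimicrobial propensity, and
#' search terminal extensions. All stage outputs are written to `out_dir`
#' as plain text; progress goes to standard error via `message()`. A rerun
#' with an identical config produces identical output files.
#'
#' @param config Named list (or path to a two-column `key<TAB>value` text
#'   file). Recognized keys, with defaults: `seed` (1), `n_train` (200,
#'   peptides per class), `alpha` (0.05), `cost` (1), `threshold` (0.5),
#'   `min_len` (5), `max_len` (50), `n_planted` (10), `n_background` (50),
#'   `read_length` (300), `window` (5), `propensity_threshold` (0.25),
#'   `ext_length` (4), `train_fasta` / `train_labels`, `reads_fastq`
#'   (paths; when given they replace simulation).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the fitted model, the mining report, file
#'   paths and per-stage counts.
#' @export
run_full_pipeline <- function(config = list(), out_dir = tempfile("acprun")) {
  if (is.character(config)) {
    kv <- utils::read.delim(config, header = FALSE,
                            col.names = c("key", "value"),
                            stringsAsFactors = FALSE)
    config <- stats::setNames(as.list(kv$value), kv$key)
    num <- suppressWarnings(vapply(config, function(v)
      !is.na(as.numeric(v)), logical(1)))
    config[num] <- lapply(config[num], as.numeric)
  }
  defaults <- list(seed = 1, n_train = 200, alpha = 0.05, cost = 1,
                   threshold = 0.5, min_len = 5, max_len = 50,
                   n_planted = 10, n_background = 50, read_length = 300,
                   window = 5, propensity_threshold = 0.25, ext_length = 4)
  cfg <- utils::modifyList(defaults, config)
  cfg_hash <- unname(tools::md5sum(local({
    tmp <- tempfile()
    writeLines(paste(names(cfg), unlist(cfg), sep = "="), tmp)
    tmp
  })))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(path) {
    writeLines(c(paste0("# config_hash\t", cfg_hash),
                 readLines(path, warn = FALSE)), path)
  }
  seed <- as.integer(cfg$seed)

  message("[acpmine] stage 1/7: training data")
  if (!is.null(cfg$train_fasta)) {
    recs <- read_fasta(cfg$train_fasta, "protein")
    labels <- sub("^label=", "", recs$description)
    table <- featurize_set(recs$sequence, labels)
  } else {
    table <- sample_training_set(cfg$n_train, seed)
  }
  message("  ", nrow(table), " labelled peptides featurized")

  message("[acpmine] stage 2/7: feature selection")
  sel <- select_features(table, alpha = cfg$alpha)
  sel_path <- file.path(out_dir, "selected_features.tsv")
  write_selection(sel, sel_path); stamp(sel_path)
  message("  ", sum(sel$selected), " of ", attr(sel, "m"),
          " testable features selected at alpha = ", cfg$alpha)

  message("[acpmine] stage 3/7: classifier fit")
  model <- acp_fit(table, cost = cfg$cost, seed = seed,
                   threshold = cfg$threshold, alpha = cfg$alpha)
  model_path <- file.path(out_dir, "model.txt")
  save_model(model, model_path)

  message("[acpmine] stage 4/7: reads")
  if (!is.null(cfg$reads_fastq)) {
    reads <- read_fastq(cfg$reads_fastq)
    manifest <- NULL
  } else {
    planted <- sample_peptides(class_profile("acp", c(20L, 40L)),
                               cfg$n_planted, seed + 2L)$sequence
    sim <- generate_reads(planted, cfg$n_background, cfg$read_length,
                          seed + 3L)
    reads <- sim$reads
    manifest <- sim$manifest
    write_synthetic_reads(sim, file.path(out_dir, "reads.fastq"),
                          file.path(out_dir, "manifest.tsv"))
  }
  message("  ", nrow(reads), " reads")

  message("[acpmine] stage 5/7: candidate mining")
  mining <- mine_reads(reads, model, min_len = cfg$min_len,
                       max_len = cfg$max_len)
  cand_path <- file.path(out_dir, "candidates.tsv")
  write_candidates(mining, cand_path, top_n = 25L); stamp(cand_path)
  message("  ", paste(names(mining$stage_counts), mining$stage_counts,
                      sep = "=", collapse = ", "))
  if (!nrow(mining$candidates)) {
    message("[acpmine] no candidates; stopping after mining")
    return(invisible(list(model = model, mining = mining, config = cfg,
                          config_hash = cfg_hash, out_dir = out_dir)))
  }
  top <- mining$candidates$peptide[1L]

  message("[acpmine] stage 6/7: top-candidate characterization")
  props <- property_report(top)
  prop_path <- file.path(out_dir, "top_candidate_properties.txt")
  write_properties(props, prop_path); stamp(prop_path)
  scan <- scan_propensity(top, window = cfg$window,
                          threshold = cfg$propensity_threshold)
  scan_path <- file.path(out_dir, "top_candidate_propensity.tsv")
  write_profile(scan, scan_path); stamp(scan_path)

  message("[acpmine] stage 7/7: terminal-extension search")
  ext <- search_extensions(top, length = cfg$ext_length, model = model)
  ext_path <- file.path(out_dir, "extensions.tsv")
  utils::write.table(ext$candidates, ext_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  stamp(ext_path)
  message("[acpmine] done; outputs in ", out_dir)
  invisible(list(model = model, mining = mining, properties = props,
                 propensity = scan, extensions = ext, manifest = manifest,
                 config = cfg, config_hash = cfg_hash, out_dir = out_dir))
}
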