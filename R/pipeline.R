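run_config_defaults <- function() {
  list(
    seed = 1L,
    log_level = "info",
    outdir = ".",
    simulate = list(enabled = FALSE, n_genomes = 10L, n_clades = 2L,
                    n_truncated = 0L),
    inputs = list(fasta_dir = NULL, gff_dir = NULL),
    extraction = unclass(extraction_config()),
    clustering = list(k = 2L, linkage = "wpgma", w_seq = 0.5, w_str = 0.5),
    consensus = list(tau = 0.5, beta = 1, gamma = 1, delta = 0.5, min_loop = 3L),
    hlt = list(threshold = 17L, boxA_motif = BOXA_MOTIF, boxA_max_mm = 2L))
}

validate_scalar <- function(value, name, type, errors, min = NULL) {
  ok <- switch(type,
               int = is.numeric(value) && length(value) == 1 &&
                 value == round(value),
               num = is.numeric(value) && length(value) == 1,
               chr = is.character(value) && length(value) == 1,
               lgl = is.logical(value) && length(value) == 1,
               intv = is.numeric(value) && length(value) == 2 &&
                 value[1] <= value[2])
  if (!ok) return(c(errors, sprintf("%s: expected %s", name, type)))
  if (!is.null(min) && type %in% c("int", "num") && value < min) {
    return(c(errors, sprintf("%s: must be >= %s", name, min)))
  }
  errors
}

config_schema <- function() {
  # name -> c(type, min) ; nested keys dotted
  list(
    seed = c("int", 0), log_level = c("chr", NA), outdir = c("chr", NA),
    `simulate.enabled` = c("lgl", NA), `simulate.n_genomes` = c("int", 1),
    `simulate.n_clades` = c("int", 1), `simulate.n_truncated` = c("int", 0),
    `inputs.fasta_dir` = c("chr", NA), `inputs.gff_dir` = c("chr", NA),
    `extraction.trailer_anchor` = c("chr", NA),
    `extraction.trailer_anchor_max_mm` = c("int", 0),
    `extraction.trailer_window` = c("intv", NA),
    `extraction.trailer_slice` = c("intv", NA),
    `extraction.trailer_from` = c("chr", NA),
    `extraction.boxC_motif` = c("chr", NA),
    `extraction.boxC_max_mm` = c("int", 0),
    `extraction.boxC_window` = c("intv", NA),
    `extraction.leader_upstream_pad` = c("int", 1),
    `extraction.leader_into_gene` = c("int", 1),
    `extraction.min_total_len` = c("int", 0),
    `extraction.spacer` = c("chr", NA),
    `extraction.edge_margin` = c("int", 0),
    `clustering.k` = c("int", 1), `clustering.linkage` = c("chr", NA),
    `clustering.w_seq` = c("num", 0), `clustering.w_str` = c("num", 0),
    `consensus.tau` = c("num", 0), `consensus.beta` = c("num", 0),
    `consensus.gamma` = c("num", 0), `consensus.delta` = c("num", 0),
    `consensus.min_loop` = c("int", 0),
    `hlt.threshold` = c("int", 0), `hlt.boxA_motif` = c("chr", NA),
    `hlt.boxA_max_mm` = c("int", 0))
}

#' Validate a run configuration
#'
#' Reads a YAML file (or takes a list), fills every unset key from the
#' defaults, rejects unknown keys by name, and enumerates all schema
#' violations instead of stopping at the first. An empty file yields the
#' full default configuration.
#'
#' @param config path to a YAML file, or a (possibly partial) config list.
#' @return a validated `run_config` list.
#' @export
validate_run_config <- function(config = list()) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config) %||% list()
  }
  defaults <- run_config_defaults()
  errors <- character()
  unknown <- setdiff(names(config), names(defaults))
  for (k in unknown) errors <- c(errors, sprintf("unknown key '%s'", k))
  merged <- defaults
  for (k in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[k]])) {
      sub <- config[[k]]
      if (!is.list(sub)) {
        errors <- c(errors, sprintf("%s: expected a mapping", k))
        next
      }
      bad <- setdiff(names(sub), names(defaults[[k]]))
      for (b in bad) errors <- c(errors, sprintf("unknown key '%s.%s'", k, b))
      for (s in intersect(names(sub), names(defaults[[k]]))) {
        merged[[k]][[s]] <- sub[[s]]
      }
    } else {
      merged[[k]] <- config[[k]]
    }
  }
  schema <- config_schema()
  for (key in names(schema)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    value <- if (length(parts) == 1) merged[[parts]] else
      merged[[parts[1]]][[parts[2]]]
    if (is.null(value)) next # nullable (input dirs)
    min <- suppressWarnings(as.numeric(schema[[key]][2]))
    errors <- validate_scalar(value, key, schema[[key]][1], errors,
                              min = if (is.na(min)) NULL else min)
  }
  if (length(errors) > 0) {
    abort(paste(c("invalid configuration:", errors), collapse = "\n  "))
  }
  structure(merged, class = "run_config")
}

log_msg <- function(level, cfg_level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[cfg_level %||% "info"]]) {
    message(sprintf("[%s] %s", level, sprintf(...)))
  }
}

#' Run the full flank-analysis pipeline
#'
#' simulate (optional) -> extract -> cluster -> per-clade consensus
#' covariation -> hLT profiling, with artifacts persisted under
#' `config$outdir` and a machine-readable report returned (and written as
#' `report.json`). The report records per-stage counts, the configuration
#' hash and the seed; rerunning with the same config and inputs reproduces
#' it bit for bit.
#'
#' @param config a path, list, or validated [validate_run_config()] result.
#' @return the run report (list), invisibly the same as `report.json`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else
    validate_run_config(config)
  set.seed(cfg$seed)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- digest_config(cfg)
  report <- list(config_hash = cfg_hash, seed = cfg$seed, stages = list())
  lv <- cfg$log_level
  # --- inputs
  if (isTRUE(cfg$simulate$enabled)) {
    log_msg("info", lv, "simulating %d genomes in %d clades",
            cfg$simulate$n_genomes, cfg$simulate$n_clades)
    sim <- simulate_genomes(cfg$simulate$n_genomes, cfg$simulate$n_clades,
                            seed = cfg$seed,
                            n_truncated = cfg$simulate$n_truncated,
                            outdir = file.path(cfg$outdir, "sim"))
    contigs <- sim$contigs
    features <- sim$features
    report$stages$simulate <- list(genomes = cfg$simulate$n_genomes,
                                   genes = nrow(features))
  } else {
    if (is.null(cfg$inputs$fasta_dir) || is.null(cfg$inputs$gff_dir)) {
      abort("stage extract: no inputs (set inputs.fasta_dir/gff_dir or simulate.enabled)")
    }
    fas <- list.files(cfg$inputs$fasta_dir, "\\.(fa|fasta|fna)$",
                      full.names = TRUE)
    gffs <- list.files(cfg$inputs$gff_dir, "\\.gff3?$", full.names = TRUE)
    contigs <- dplyr::bind_rows(purrr::map(fas, read_fasta))
    features <- dplyr::bind_rows(purrr::map(gffs, function(g) {
      read_gff3_16s(g, contigs)
    }))
  }
  # --- extract
  ecfg <- do.call(extraction_config, cfg$extraction)
  pairs <- extract_flank_pairs(contigs, features, ecfg)
  write_flank_pairs(pairs, tsv = file.path(cfg$outdir, "pairs.tsv"),
                    fasta = file.path(cfg$outdir, "pairs.fasta"))
  report$stages$extract <- attr(pairs, "report")
  log_msg("info", lv, "extract: %d/%d pairs kept",
          sum(pairs$kept), nrow(pairs))
  kept <- dplyr::filter(pairs, .data$kept)
  # --- cluster
  k <- cfg$clustering$k
  if (k > nrow(kept)) {
    abort(sprintf("stage cluster: k = %d exceeds the %d kept pairs", k,
                  nrow(kept)))
  }
  D <- flank_distances(pairs, weights = c(seq = cfg$clustering$w_seq,
                                          str = cfg$clustering$w_str))
  tree <- build_tree(D, linkage = cfg$clustering$linkage)
  write_newick(tree, file.path(cfg$outdir, "tree.nwk"))
  clades <- cut_tree(tree, k)
  write.table(clades, file.path(cfg$outdir, "clades.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report$stages$cluster <- list(k = k,
                                sizes = as.integer(table(clades$clade)))
  # --- covary
  seqs <- setNames(kept$combined, paste0(kept$assembly_id, "|",
                                         kept$gene_id))
  models_dir <- file.path(cfg$outdir, "models")
  dir.create(models_dir, showWarnings = FALSE)
  consensus_pairs_n <- integer(0)
  for (cl in sort(unique(clades$clade))) {
    ids <- clades$id[clades$clade == cl]
    if (length(ids) < 2) {
      consensus_pairs_n[as.character(cl)] <- NA_integer_
      next
    }
    m <- consensus_model(seqs[ids], tau = cfg$consensus$tau,
                         beta = cfg$consensus$beta,
                         gamma = cfg$consensus$gamma,
                         delta = cfg$consensus$delta,
                         min_loop = cfg$consensus$min_loop)
    covariation_report(m, file.path(models_dir, sprintf("clade_%d", cl)))
    consensus_pairs_n[as.character(cl)] <- nrow(m$consensus$pairs)
  }
  report$stages$covary <- list(clades = length(unique(clades$clade)),
                               consensus_pairs = as.list(consensus_pairs_n))
  # --- hlt
  profiles <- profile_flank_pairs(pairs, threshold = cfg$hlt$threshold,
                                  boxA_motif = cfg$hlt$boxA_motif,
                                  boxA_max_mm = cfg$hlt$boxA_max_mm)
  write_profiles(profiles, file.path(cfg$outdir, "profiles.tsv"))
  report$stages$hlt <- as.list(glance(profiles))
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

digest_config <- function(cfg) {
  # stable content hash without external digest packages
  s <- paste(utils::capture.output(utils::str(cfg, give.attr = FALSE)),
             collapse = "\n")
  raw <- utils::head(charToRaw(s), 1e6)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251)) %%
            .Machine$integer.max)
}
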