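#' @title Configuration, table I/O and pipeline orchestration
#' @name pipeline_cli
#' @description
#' YAML/JSON configuration with strict schema checks, schema-validated
#' CSV/TSV/MTX table I/O shared by all modules, and an end-to-end driver
#' running synth -> fit -> simulate -> score -> classify with per-stage
#' checksum skipping.  Seeds are mandatory; every run writes its resolved
#' configuration next to its outputs.
NULL

.config_schema <- list(
  seed = "numeric", out_dir = "character", stages = "character",
  model = "character", n_iter = "numeric", burn_in = "numeric",
  n_cells = "numeric", n_replicates = "numeric",
  bin_size = "numeric", n_random = "numeric",
  nu1 = "numeric", k_on_bar = "numeric",
  simulator = "list", synth = "list")

#' Read and validate an analysis configuration
#'
#' @param path path to a YAML or JSON configuration file
#' @return validated named list of class `analysis_config`
#' @export
read_config <- function(path) {
  .check(file.exists(path), "config file not found: %s", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
    else yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg a configuration list
#' @export
validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(.config_schema))
  .check(length(unknown) == 0, "unknown config keys: %s",
         paste(unknown, collapse = ", "))
  .check(!is.null(cfg$seed), "config must set a seed (no silent nondeterminism)")
  for (nm in names(cfg)) {
    want <- .config_schema[[nm]]
    ok <- switch(want, numeric = is.numeric(cfg[[nm]]),
                 character = is.character(cfg[[nm]]), list = is.list(cfg[[nm]]))
    .check(isTRUE(ok), "config key '%s' must be %s", nm, want)
  }
  defaults <- list(stages = "synth", model = "negative_binomial",
                   n_iter = 2000, n_cells = 1000, n_replicates = 2,
                   bin_size = 2000, n_random = 1000, nu1 = 4.5)
  cfg <- modifyList(defaults, cfg)
  structure(cfg, class = "analysis_config")
}

#' Schema-checked table reading and writing
#'
#' @param path file path (`.csv` or `.tsv`)
#' @param schema named character vector mapping required column names to
#'   types (`"numeric"`, `"integer"`, `"character"`)
#' @return data frame with exactly the schema columns, coerced to the
#'   declared types
#' @export
read_table_checked <- function(path, schema) {
  .check(file.exists(path), "table not found: %s", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  d <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                check.names = FALSE)
  missing <- setdiff(names(schema), names(d))
  .check(length(missing) == 0, "table %s lacks required column(s): %s",
         path, paste(missing, collapse = ", "))
  for (nm in names(schema)) {
    d[[nm]] <- switch(schema[[nm]],
                      numeric = as.double(d[[nm]]),
                      integer = as.integer(d[[nm]]),
                      character = as.character(d[[nm]]))
    .check(!(schema[[nm]] %in% c("numeric", "integer")) ||
             !anyNA(d[[nm]]) || anyNA(read.csv(path, sep = sep)[[nm]]),
           "column '%s' of %s is not %s", nm, path, schema[[nm]])
  }
  d[names(schema)]
}

#' @rdname read_table_checked
#' @param d data frame to write
#' @export
write_table_checked <- function(d, path, schema) {
  missing <- setdiff(names(schema), names(d))
  .check(length(missing) == 0, "data lacks required column(s): %s",
         paste(missing, collapse = ", "))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(d[names(schema)], path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write / read an interaction matrix as MatrixMarket plus a JSON sidecar
#'
#' @param mat an [interaction_matrix()]
#' @param dir output directory (one matrix per chromosome)
#' @return (`write`) the directory; (`read`) the matrix
#' @export
write_interaction_matrix <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(dir, paste0("chr", mat$chrom, ".mtx"))
  Matrix::writeMM(methods::as(mat$m, "generalMatrix"), f)
  jsonlite::write_json(list(chrom = mat$chrom, bin_size = mat$bin_size,
                            n_bins = mat$n_bins),
                       file.path(dir, paste0("chr", mat$chrom, ".json")),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_interaction_matrix
#' @param chrom chromosome label to read
#' @param bin_size expected bin size; a sidecar mismatch is an error
#' @export
read_interaction_matrix <- function(dir, chrom, bin_size = NULL) {
  f <- file.path(dir, paste0("chr", chrom, ".mtx"))
  sc <- file.path(dir, paste0("chr", chrom, ".json"))
  .check(file.exists(f) && file.exists(sc), "matrix or sidecar missing in %s",
         dir)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!is.null(bin_size))
    .check(meta$bin_size == bin_size,
           "sidecar bin size %s does not match requested %s",
           meta$bin_size, bin_size)
  m <- methods::as(Matrix::readMM(f), "CsparseMatrix")
  idx <- Matrix::which(m != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]   # upper triangle once
  interaction_matrix(meta$chrom, meta$bin_size,
                     bins_i = idx[, 1] - 1L, bins_j = idx[, 2] - 1L,
                     counts = m[idx], n_bins = meta$n_bins)
}

.stage_token <- function(dir, stage) file.path(dir, paste0(".", stage, ".done"))

.stage_fresh <- function(dir, stage, cfg_hash) {
  tok <- .stage_token(dir, stage)
  file.exists(tok) && identical(readLines(tok, warn = FALSE)[1], cfg_hash)
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages in dependency order on fully synthetic
#' inputs; each stage writes its outputs plus a checksum token so that
#' re-running a completed pipeline is a no-op.  The resolved configuration,
#' seed and package version are written next to the outputs.
#'
#' @param config an `analysis_config` (see [read_config()]) or a path
#' @param out_dir output directory (overrides `config$out_dir`)
#' @return the output directory, invisibly; a `summary.json` records what
#'   ran
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_config(config) else
    validate_config(unclass(config))
  dir <- out_dir %||% cfg$out_dir %||% stop("no output directory configured")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- digest::digest(cfg)
  resolved <- c(unclass(cfg), list(
    package_version = as.character(utils::packageVersion("burstloop"))))
  jsonlite::write_json(resolved, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  ran <- character(0)
  stages <- cfg$stages
  spec <- do.call(synth_spec, c(list(seed = cfg$seed,
                                     n_cells = cfg$n_cells,
                                     n_replicates = cfg$n_replicates),
                                cfg$synth %||% list()))

  if ("synth" %in% stages && !.stage_fresh(dir, "synth", cfg_hash)) {
    ff <- synth_flowfish(spec)
    for (k in seq_along(ff$replicates)) {
      r <- ff$replicates[[k]]
      d <- data.frame(cell_id = seq_along(r$fluorescence),
                      fluorescence = r$fluorescence)
      if (!is.null(r$dna_content)) d$dna_content <- r$dna_content
      if (!is.null(r$fsc_a)) d$fsc_a <- r$fsc_a
      write.csv(d, file.path(dir, sprintf("cells_rep%d.csv", k)),
                row.names = FALSE)
    }
    ctrl <- synth_control(spec)
    write.csv(data.frame(cell_id = seq_along(ctrl$values),
                         fluorescence = ctrl$values),
              file.path(dir, "control.csv"), row.names = FALSE)
    write.csv(synth_calibration(spec), file.path(dir, "calibration.csv"),
              row.names = FALSE)
    ia <- synth_interaction_data(spec)
    write_interaction_matrix(ia$matrix, file.path(dir, "matrix"))
    write.csv(ia$annotation, file.path(dir, "genes.csv"), row.names = FALSE)
    jsonlite::write_json(list(seed = spec$seed, truth = ia$truth),
                         file.path(dir, "truth_interactions.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(cfg_hash, .stage_token(dir, "synth"))
    ran <- c(ran, "synth")
  }

  if ("fit" %in% stages && !.stage_fresh(dir, "fit", cfg_hash)) {
    ctrl <- read_table_checked(file.path(dir, "control.csv"),
                               c(cell_id = "integer",
                                 fluorescence = "numeric"))
    bg <- fit_background(ctrl$fluorescence)
    calib <- calibrate_kappa_prior(
      read_table_checked(file.path(dir, "calibration.csv"),
                         c(count = "numeric", fluorescence = "numeric")))
    priors <- default_priors(cfg$model, calib = calib, background = bg)
    reps <- lapply(seq_len(cfg$n_replicates), function(k) {
      d <- read_table_checked(file.path(dir, sprintf("cells_rep%d.csv", k)),
                              c(cell_id = "integer",
                                fluorescence = "numeric"))
      flowfish_dataset(d$fluorescence, replicate_id = k)
    })
    ch <- fit_consensus(reps, kind = cfg$model, priors = priors,
                        backgrounds = list(bg), n_iter = cfg$n_iter,
                        seed = sub_seed(cfg$seed, 2L))
    s <- posterior_summary(ch)
    write_table_checked(s, file.path(dir, "posterior_summary.csv"),
                        c(parameter = "character", median = "numeric",
                          hpd_lo = "numeric", hpd_hi = "numeric"))
    writeLines(cfg_hash, .stage_token(dir, "fit"))
    ran <- c(ran, "fit")
  }

  if ("simulate" %in% stages && !.stage_fresh(dir, "simulate", cfg_hash)) {
    sim <- do.call(micro_params, cfg$simulator %||% list())
    tab <- noise_scan(sim, n_grid = c(0.5, 5, 50), l_grid = c(0, 0.95),
                      n_cells = 200L, seed = sub_seed(cfg$seed, 3L))
    write.csv(tab, file.path(dir, "noise_scan.csv"), row.names = FALSE)
    writeLines(cfg_hash, .stage_token(dir, "simulate"))
    ran <- c(ran, "simulate")
  }

  if ("chia_score" %in% stages && !.stage_fresh(dir, "chia_score", cfg_hash)) {
    mat <- read_interaction_matrix(file.path(dir, "matrix"), "1",
                                   bin_size = cfg$bin_size)
    ann <- read.csv(file.path(dir, "genes.csv"), stringsAsFactors = FALSE)
    genes <- filter_genes(ann, bin_size = cfg$bin_size)
    sc <- score_genes(mat, genes, n_samples = cfg$n_random,
                      seed = sub_seed(cfg$seed, 4L))
    write_table_checked(sc, file.path(dir, "interaction_scores.csv"),
                        c(symbol = "character", raw_count = "numeric",
                          ratio = "numeric", score = "numeric"))
    writeLines(cfg_hash, .stage_token(dir, "chia_score"))
    ran <- c(ran, "chia_score")
  }

  if ("sc_noise" %in% stages && !.stage_fresh(dir, "sc_noise", cfg_hash)) {
    um <- synth_umi(spec)
    labels <- infection_split(um$matrix)
    cn <- condition_noise_table(um$matrix, labels)
    write.csv(cn$table, file.path(dir, "condition_noise.csv"),
              row.names = FALSE)
    writeLines(cfg_hash, .stage_token(dir, "sc_noise"))
    ran <- c(ran, "sc_noise")
  }

  if ("classify" %in% stages && !.stage_fresh(dir, "classify", cfg_hash)) {
    um <- synth_umi(spec)
    est <- moments_negbin(um$matrix)
    est <- est[is.finite(est$CV2_X) & est$CV2_X > 0, ]
    kbar <- cfg$k_on_bar %||%
      mean(est$k_on[is.finite(est$k_on) & est$k_on > 0])
    nu <- nu_distance(est$mu_X, est$CV2_X, kbar)
    out <- data.frame(symbol = est$symbol, mu_X = est$mu_X,
                      CV2_X = est$CV2_X, nu = nu,
                      group = as.character(classify_noise(nu, cfg$nu1)))
    write_table_checked(out, file.path(dir, "noise_groups.csv"),
                        c(symbol = "character", mu_X = "numeric",
                          CV2_X = "numeric", nu = "numeric",
                          group = "character"))
    writeLines(cfg_hash, .stage_token(dir, "classify"))
    ran <- c(ran, "classify")
  }

  jsonlite::write_json(list(ran = ran, seed = cfg$seed, hash = cfg_hash),
                       file.path(dir, "summary.json"), auto_unbox = TRUE)
  invisible(dir)
}
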