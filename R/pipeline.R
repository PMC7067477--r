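#' Run configuration for the pipeline
#'
#' Collects everything [run_pipeline()] needs: the two input structures,
#' the method thresholds and the output options.
#'
#' @param path_a,path_b PDB files for conformations A and B.
#' @param chain_a,chain_b Chain identifiers.
#' @param params A [dcm_params()].
#' @param fraction_mode Denominator mode for the changed-contact
#'   fraction (`"union"`, `"mean"` or `"min"`).
#' @param domains_path Optional domain annotation CSV ([read_domains()]).
#' @param output_dir Directory for the result files (created if needed).
#' @param plot Write a PNG of the filtered difference map?
#' @param model_a_index,model_b_index MODEL number for multi-model files.
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(path_a, chain_a, path_b, chain_b,
                       params = dcm_params(), fraction_mode = "union",
                       domains_path = NULL, output_dir = tempfile("dcm_run_"),
                       plot = FALSE, model_a_index = 1L, model_b_index = 1L,
                       log_level = c("info", "quiet")) {
  for (p in c(path_a, path_b))
    if (!file.exists(p)) stop("input file not found: ", p)
  if (!is.null(domains_path) && !file.exists(domains_path))
    stop("domain annotation file not found: ", domains_path)
  structure(
    list(path_a = path_a, chain_a = chain_a, path_b = path_b,
         chain_b = chain_b, params = params, fraction_mode = fraction_mode,
         domains_path = domains_path, output_dir = output_dir, plot = plot,
         model_a_index = model_a_index, model_b_index = model_b_index,
         log_level = match.arg(log_level)),
    class = "run_config"
  )
}

#' Run the full pipeline and write result files
#'
#' Parse, align, compatibility check, contact maps, difference map,
#' filter, DSRs, metrics — then writes into `config$output_dir`:
#' `contacts.csv` (one row per conformation-exclusive contact, with both
#' models' author numbering, the per-conformation distances, the change
#' and the filtered flag), `pair_metadata.csv` (one row of identifiers,
#' pairing and mismatch statistics, RMSD, contact counts, changed
#' fraction), optionally `difference_map.png`, and `run.log`. Both CSVs
#' start with a `#` comment line embedding the tool version and
#' parameter values; rows are sorted by mapped position pair, so reruns
#' are byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `status` (`"ok"`, `"incompatible"`),
#'   `exit_code` (0 success, 3 incompatible pair), `comparison` (the
#'   [dcm_compare()] object), `summary` and `files` (paths written).
#'   I/O and parse failures raise errors.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = log_path, sep = "", append = TRUE)
    if (config$log_level == "info") message(line)
  }
  logf("diffcontact %s", utils::packageVersion("diffcontact"))
  logf("A: %s chain %s (model %d); B: %s chain %s (model %d)",
       config$path_a, config$chain_a, config$model_a_index,
       config$path_b, config$chain_b, config$model_b_index)

  model_a <- read_structure(config$path_a, config$chain_a,
                            model = config$model_a_index)
  model_b <- read_structure(config$path_b, config$chain_b,
                            model = config$model_b_index)
  domains <- if (!is.null(config$domains_path))
    read_domains(config$domains_path) else NULL

  cmp <- dcm_compare(model_a, model_b, params = config$params,
                     domains = domains, fraction_mode = config$fraction_mode)
  s <- summary(cmp)
  hdr <- paste0("# ", format_params_line(config$params, config$fraction_mode))
  files <- character(0)

  meta_path <- file.path(config$output_dir, "pair_metadata.csv")
  meta <- data.frame(
    id_a = s$id_a, id_b = s$id_b, compatible = s$compatible,
    n_pairs = s$n_pairs, mismatch_fraction = s$mismatch_fraction,
    rmsd = s$rmsd, n_contacts_a = s$n_contacts_a,
    n_contacts_b = s$n_contacts_b, n_diff = s$n_diff,
    n_filtered = s$n_filtered, n_a_only_filtered = s$n_a_only_filtered,
    n_b_only_filtered = s$n_b_only_filtered, n_dsrs = s$n_dsrs,
    changed_fraction = s$changed_fraction,
    contact_threshold = config$params$contact_threshold,
    delta_threshold = config$params$delta_threshold,
    mismatch_tolerance = config$params$mismatch_tolerance,
    min_seq_separation = config$params$min_seq_separation,
    fraction_mode = config$fraction_mode
  )
  writeLines(hdr, meta_path)
  suppressWarnings(utils::write.table(meta, meta_path, sep = ",",
                                      row.names = FALSE, append = TRUE))
  files <- c(files, metadata = meta_path)

  if (!cmp$compatible) {
    logf("pair incompatible: %s", cmp$verdict$reason)
    return(invisible(list(status = "incompatible", exit_code = 3L,
                          comparison = cmp, summary = s, files = files)))
  }

  contacts_path <- file.path(config$output_dir, "contacts.csv")
  writeLines(hdr, contacts_path)
  suppressWarnings(utils::write.table(as.data.frame(cmp), contacts_path,
                                      sep = ",", row.names = FALSE,
                                      append = TRUE))
  files <- c(files, contacts = contacts_path)

  if (!is.null(cmp$interdomain)) {
    dom_path <- file.path(config$output_dir, "interdomain.csv")
    writeLines(hdr, dom_path)
    suppressWarnings(utils::write.table(cmp$interdomain, dom_path, sep = ",",
                                        row.names = FALSE, append = TRUE))
    files <- c(files, interdomain = dom_path)
  }

  if (isTRUE(config$plot)) {
    png_path <- file.path(config$output_dir, "difference_map.png")
    grDevices::png(png_path, width = 800, height = 800)
    plot(cmp)
    grDevices::dev.off()
    files <- c(files, plot = png_path)
  }

  logf("done: %d exclusive contacts, %d filtered, %d DSRs",
       s$n_diff, s$n_filtered, s$n_dsrs)
  invisible(list(status = "ok", exit_code = 0L, comparison = cmp,
                 summary = s, files = files))
}

#' Summarize a batch of conformational pairs
#'
#' Runs the comparison for every row of a manifest and collects one
#' metadata row per pair into a single CSV — the batch counterpart of
#' [run_pipeline()] for surveying many pairs.
#'
#' @param manifest Path to a CSV with columns `path_a`, `chain_a`,
#'   `path_b`, `chain_b`, or a `data.frame` of the same shape.
#' @param output Path of the combined metadata CSV to write (`NULL` to
#'   skip writing).
#' @param params A [dcm_params()].
#' @param fraction_mode Denominator mode for the changed fraction.
#' @return The combined metadata `data.frame`, invisibly when `output`
#'   is written.
#' @export
run_batch <- function(manifest, output = NULL, params = dcm_params(),
                      fraction_mode = "union") {
  m <- if (is.data.frame(manifest)) manifest
       else utils::read.csv(manifest, comment.char = "#",
                            stringsAsFactors = FALSE)
  stopifnot(all(c("path_a", "chain_a", "path_b", "chain_b") %in% names(m)))
  rows <- lapply(seq_len(nrow(m)), function(r) {
    cfg <- run_config(m$path_a[r], m$chain_a[r], m$path_b[r], m$chain_b[r],
                      params = params, fraction_mode = fraction_mode,
                      log_level = "quiet")
    res <- run_pipeline(cfg)
    p <- file.path(cfg$output_dir, "pair_metadata.csv")
    utils::read.csv(p, comment.char = "#", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(output)) {
    writeLines(paste0("# ", format_params_line(params, fraction_mode)), output)
    suppressWarnings(utils::write.table(out, output, sep = ",",
                                        row.names = FALSE, append = TRUE))
    return(invisible(out))
  }
  out
}

#' Download a PDB entry (convenience)
#'
#' Fetches `https://files.rcsb.org/download/<ID>.pdb`. Network access is
#' a convenience only: every computation in the package runs on local
#' files.
#'
#' @param pdb_id Four-character PDB identifier.
#' @param destdir Directory to save into.
#' @return The path of the downloaded file.
#' @export
fetch_pdb <- function(pdb_id, destdir = tempdir()) {
  stopifnot(grepl("^[0-9][A-Za-z0-9]{3}$", pdb_id))
  dest <- file.path(destdir, paste0(toupper(pdb_id), ".pdb"))
  if (file.exists(dest)) return(dest)
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(pdb_id))
  utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  dest
}
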