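#' Write trajectory and dive tables
#'
#' Delimited text tables: `tracks.tsv` (raft_id, bird_id, time_s, x_bl,
#' y_bl) and `dives.tsv` (raft_id, bird_id, time_s, x_bl, y_bl,
#' heading_deg), plus `meta.json`.
#'
#' @param dataset A [raft_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_raft_tables <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pt <- file.path(dir, "tracks.tsv")
  pd <- file.path(dir, "dives.tsv")
  pm <- file.path(dir, "meta.json")
  utils::write.table(dataset$tracks, pt, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(dataset$dives, pd, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- dataset$meta
  meta$params <- if (!is.null(meta$params)) unclass(meta$params)
  jsonlite::write_json(meta, pm, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(pt, pd, pm))
}

#' Read trajectory and dive tables
#'
#' @param dir Directory written by [write_raft_tables()] (or containing
#'   equivalent delimited tables).
#' @return A [raft_dataset()].
#' @export
read_raft_tables <- function(dir) {
  tracks <- utils::read.table(file.path(dir, "tracks.tsv"), header = TRUE,
                              sep = "\t")
  dives <- utils::read.table(file.path(dir, "dives.tsv"), header = TRUE,
                             sep = "\t")
  meta_file <- file.path(dir, "meta.json")
  meta <- if (file.exists(meta_file))
    jsonlite::read_json(meta_file, simplifyVector = TRUE) else list()
  raft_dataset(tracks, dives, meta = meta)
}

#' Write posterior samples and summaries
#'
#' The samples go to a delimited table (iteration, the five parameters,
#' log-likelihood); the summary, acceptance rates and settings to a JSON
#' sidecar.
#'
#' @param fit A [run_mcmc()] result.
#' @param file Output path for the sample table; the sidecar is
#'   `<file>.json`.
#' @return Invisibly, `file`.
#' @export
write_posterior <- function(fit, file) {
  tab <- data.frame(iteration = seq_len(nrow(fit$samples)), fit$samples,
                    loglik = fit$loglik)
  utils::write.table(tab, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(variant = fit$variant, summary = fit$summary,
         acceptance = as.list(fit$acceptance), burn = fit$burn,
         draws = fit$draws, seed = fit$seed, n_records = fit$n_records,
         n_dived = fit$n_dived),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' Write / read a configuration as YAML
#'
#' @param config A [raft_config()] (or plain list).
#' @param file Path to a YAML file.
#' @return `write_config` invisibly returns `file`; `read_config` returns
#'   a [raft_config()].
#' @export
write_config <- function(config, file) {
  x <- unclass(config)
  if (!is.null(x$dive_params)) x$dive_params <- unclass(x$dive_params)
  yaml::write_yaml(x, file)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  x <- yaml::read_yaml(file)
  dp <- do.call(dive_params, x$dive_params)
  x$dive_params <- dp
  do.call(raft_config, x)
}
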