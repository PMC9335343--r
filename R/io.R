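#' Write a trajectory to tidy TSV tables
#'
#' Writes `summary.tsv` (generation, trait_mean, var_genetic),
#' `locus_paths.tsv` (generation, locus, freq; if any were recorded), and a
#' `manifest.json` with the run parameters, into `dir`.
#'
#' @param traj A `wf_trajectory`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  stopifnot(inherits(traj, "wf_trajectory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(traj$summary, file.path(dir, "summary.tsv"))
  if (nrow(traj$locus_paths)) {
    readr::write_tsv(traj$locus_paths, file.path(dir, "locus_paths.tsv"))
  }
  par <- traj$params
  manifest <- list(
    n = par$n, mu = par$mu, Vs = par$Vs,
    optimum = par$optimum, generations = par$generations,
    seed = par$seed, engine = par$engine, selection = par$selection,
    beta = par$beta, sel_method = par$sel_method,
    L = nrow(traj$arch), centering = attr(traj$arch, "centering"),
    record_every = traj$record_every, locus_filter = traj$locus_filter
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read back trajectory tables written by [write_trajectory()]
#'
#' @param dir Directory written by [write_trajectory()].
#' @return A list with `summary`, `locus_paths` (possibly empty), and the
#'   `manifest` list.
#' @export
read_trajectory_tables <- function(dir) {
  lp_path <- file.path(dir, "locus_paths.tsv")
  list(
    summary = readr::read_tsv(file.path(dir, "summary.tsv"),
                              show_col_types = FALSE),
    locus_paths = if (file.exists(lp_path)) {
      readr::read_tsv(lp_path, show_col_types = FALSE)
    } else {
      tibble::tibble(generation = integer(), locus = integer(),
                     freq = numeric())
    },
    manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                   simplifyVector = TRUE)
  )
}
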