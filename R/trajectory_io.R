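#' Write a trajectory to CSV with a JSON sidecar
#'
#' The CSV holds the columns `time_years`, `A`, `J`, `F`, `qE`; the sidecar
#' `<path>.json` records the full parameter set, the seed and the noise kind
#' so a run can be reproduced from its artifacts.
#'
#' @param traj An `eco_trajectory`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("time_years", "A", "J", "F", "qE")],
                   path, row.names = FALSE)
  meta <- list(params = unclass(attr(traj, "params")),
               seed = attr(traj, "seed"),
               noise_kind = attr(traj, "noise_kind"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path (the sidecar `<path>.json` is read when present).
#' @return An `eco_trajectory`.
#' @export
read_trajectory <- function(path) {
  tr <- utils::read.csv(path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(tr, "params") <- do.call(eco_params, meta$params)
    attr(tr, "seed") <- meta$seed
    attr(tr, "noise_kind") <- meta$noise_kind
  }
  class(tr) <- c("eco_trajectory", "data.frame")
  tr
}
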