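#' Export map snapshots
#'
#' Writes the snapshots recorded by [simulate_trial()] both as one CSV
#' matrix per map and time and as a single long-format CSV
#' (`t, map, i, j, rate`) convenient for animation, together with a JSON
#' metadata file (configuration hash, ablation flags, seed).
#'
#' @param trial a [simulate_trial()] result with snapshots.
#' @param dir output directory (created if needed).
#' @param config the [lip_config()] used for the run.
#' @param seed seed recorded in the metadata (or `NA`).
#' @return The directory, invisibly.
#' @export
write_map_snapshots <- function(trial, dir, config, seed = NA) {
  if (is.null(trial$snapshots) || length(trial$snapshots) == 0) {
    abort("trial has no snapshots; pass snapshot_times to simulate_trial()")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- list()
  for (tname in names(trial$snapshots)) {
    st <- trial$snapshots[[tname]]
    tval <- as.numeric(sub("^t", "", tname))
    for (map in c("xr", "xe_pc", "xe_cd", "xe_fef", "xb_pc", "xb_cd",
                  "xh")) {
      r <- st[[map]]
      mat <- if (is.matrix(r)) r else matrix(r, nrow = 1)
      write.csv(mat,
                file.path(dir, sprintf("%s_%s.csv", map, tname)),
                row.names = FALSE)
      idx <- which(mat >= 0, arr.ind = TRUE)
      long[[paste(tname, map)]] <- tibble::tibble(
        t = tval, map = map, i = idx[, 1], j = idx[, 2],
        rate = as.vector(mat))
    }
  }
  write.csv(dplyr::bind_rows(long), file.path(dir, "snapshots_long.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = config_hash(config), seed = seed,
         ablation = unclass(trial$ablation),
         times = names(trial$snapshots)),
    file.path(dir, "run_meta.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
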