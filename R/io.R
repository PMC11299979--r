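#' Tabular input/output
#'
#' All tabular data types round-trip through plain TSV files with `#`
#' metadata header lines, so analysis outputs stay text-only and
#' diffable.
#'
#' @name tagfold_io
NULL

write_tsv_meta <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in names(meta))
    writeLines(sprintf("# %s: %s", m, meta[[m]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_meta <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- sub("^#\\s*", "", m)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Write / read a denaturation curve as TSV
#'
#' @param curve a `denaturation_curve`.
#' @param path file path.
#' @return The path (write) or a `denaturation_curve` (read).
#' @export
write_curve_tsv <- function(curve, path) {
  write_tsv_meta(data.frame(axis = curve$axis, signal = curve$signal), path,
                 c(mode = curve$mode,
                   normalized = as.character(isTRUE(curve$normalized))))
}

#' @rdname write_curve_tsv
#' @export
read_curve_tsv <- function(path) {
  df <- read_tsv_meta(path)
  meta <- attr(df, "meta")
  new_denaturation_curve(df$axis, df$signal,
                         if (is.null(meta$mode)) "chemical" else meta$mode,
                         identical(meta$normalized, "TRUE"))
}

#' Write / read a proteolysis dataset as long-format TSV
#'
#' Columns: concentration (M), time (s), intensity; the no-protease
#' control lane is stored with concentration 0.
#'
#' @param dataset a `proteolysis_dataset`.
#' @param path file path.
#' @export
write_proteolysis_tsv <- function(dataset, path) {
  ctrl <- data.frame(concentration = 0, time = dataset$control$time,
                     intensity = dataset$control$intensity)
  write_tsv_meta(rbind(dataset$data, ctrl), path)
}

#' @rdname write_proteolysis_tsv
#' @export
read_proteolysis_tsv <- function(path) {
  df <- read_tsv_meta(path)
  ctrl <- df[df$concentration == 0, c("time", "intensity")]
  structure(list(data = df[df$concentration > 0, ], control = ctrl,
                 truth = NULL),
            class = "proteolysis_dataset")
}

#' Write / read an amide shift table as long-format TSV
#'
#' Columns: residue, temperature_K, shift_ppm.
#'
#' @param table a `shift_table`.
#' @param path file path.
#' @export
write_shift_tsv <- function(table, path) write_tsv_meta(table$data, path)

#' @rdname write_shift_tsv
#' @export
read_shift_tsv <- function(path) {
  structure(list(data = read_tsv_meta(path), truth = NULL),
            class = "shift_table")
}

#' Write / read a relaxation dataset as TSV
#'
#' Columns: residue, r1, r1_err, r2, r2_err, noe, noe_err; the field
#' (MHz) is stored in the metadata header.
#'
#' @param dataset a `relaxation_dataset`.
#' @param path file path.
#' @export
write_relaxation_tsv <- function(dataset, path) {
  write_tsv_meta(dataset$data, path,
                 c(field_mhz = as.character(dataset$field_mhz)))
}

#' @rdname write_relaxation_tsv
#' @export
read_relaxation_tsv <- function(path) {
  df <- read_tsv_meta(path)
  field <- as.numeric(attr(df, "meta")$field_mhz)
  structure(list(data = df, field_mhz = field, truth = NULL),
            class = "relaxation_dataset")
}

#' Export a trajectory as reference PDB plus multi-model PDB
#'
#' Uses bio3d for the PDB records; one MODEL per frame.
#'
#' @param traj a `trajectory`.
#' @param ref_path,frames_path output paths.
#' @export
write_trajectory_pdb <- function(traj, ref_path, frames_path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("bio3d is required for PDB export")
  topo <- traj$topology
  args <- list(resno = topo$residue, chain = topo$chain,
               resid = rep("GLY", nrow(topo)), elety = topo$atom)
  do.call(bio3d::write.pdb,
          c(list(xyz = as.numeric(t(traj$reference)), file = ref_path), args))
  xyz <- do.call(rbind, lapply(traj$frames, function(m) as.numeric(t(m))))
  do.call(bio3d::write.pdb, c(list(xyz = xyz, file = frames_path), args))
  invisible(frames_path)
}
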