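## Plain-text external interfaces: delimited trajectory matrices with a JSON
## manifest, one-integer-per-line discrete trajectories with a JSON sidecar,
## two-column atom-pair CSVs, and minimal CA-only multi-MODEL PDB ensembles.

#' Write feature trajectories as delimited text with a JSON manifest
#'
#' Each trajectory becomes `traj_<i>.tsv` (tab-separated, header row of
#' feature labels, one frame per row, a `# frame_interval` comment line);
#' `manifest.json` records files, frame interval and labels.
#'
#' @param trajs list of [FeatureTrajectory-class] objects.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
writeTrajectories <- function(trajs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(length(trajs))
  for (i in seq_along(trajs)) {
    files[i] <- sprintf("traj_%03d.tsv", i)
    path <- file.path(dir, files[i])
    con <- file(path, "w")
    writeLines(sprintf("# frame_interval %.17g", trajs[[i]]@frameInterval), con)
    write.table(trajs[[i]]@values, con, sep = "\t", row.names = FALSE,
                quote = FALSE)
    close(con)
  }
  manifest <- list(files = files,
                   frame_interval = trajs[[1L]]@frameInterval,
                   feature_labels = trajs[[1L]]@featureLabels)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Read feature trajectories written by [writeTrajectories()]
#'
#' @param dir directory containing `manifest.json`.
#' @return list of [FeatureTrajectory-class] objects.
#' @export
readTrajectories <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lapply(manifest$files, function(f) {
    vals <- as.matrix(read.delim(file.path(dir, f), comment.char = "#"))
    featureTrajectory(vals, frameInterval = manifest$frame_interval,
                      featureLabels = manifest$feature_labels)
  })
}

#' Write discrete state trajectories (one integer per line) with a sidecar
#'
#' @param dtrajs list of integer vectors (1-based states).
#' @param dir output directory.
#' @param nStates total number of states (default: max observed).
#' @param frameInterval time units per frame.
#' @return sidecar path, invisibly.
#' @export
writeDiscreteTrajectories <- function(dtrajs, dir,
                                      nStates = max(unlist(dtrajs)),
                                      frameInterval = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("dtraj_%03d.txt", seq_along(dtrajs))
  for (i in seq_along(dtrajs))
    writeLines(as.character(dtrajs[[i]]), file.path(dir, files[i]))
  side <- list(files = files, n_states = nStates,
               frame_interval = frameInterval)
  spath <- file.path(dir, "dtrajs.json")
  jsonlite::write_json(side, spath, auto_unbox = TRUE, digits = NA)
  invisible(spath)
}

#' Read discrete state trajectories written by [writeDiscreteTrajectories()]
#'
#' @param dir directory containing `dtrajs.json`.
#' @return list with `dtrajs`, `nStates`, `frameInterval`.
#' @export
readDiscreteTrajectories <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "dtrajs.json"),
                              simplifyVector = TRUE)
  list(dtrajs = lapply(side$files, function(f)
         as.integer(readLines(file.path(dir, f)))),
       nStates = side$n_states, frameInterval = side$frame_interval)
}

#' Write/read atom-pair sets as two-column CSV
#'
#' @param pairs two-column character matrix or data.frame of atom labels.
#' @param path CSV path.
#' @return `readAtomPairs` returns a two-column character matrix.
#' @export
writeAtomPairs <- function(pairs, path) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  colnames(pairs) <- c("atom1", "atom2")
  write.csv(pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeAtomPairs
#' @export
readAtomPairs <- function(path) {
  as.matrix(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a helix ensemble as a minimal CA-only multi-MODEL PDB
#'
#' One MODEL per conformation, ATOM records for CA atoms only (residue type
#' ALA, chain A), fixed-width PDB columns.
#'
#' @param ensemble a single n x 3 matrix or a list of them.
#' @param path output PDB path.
#' @return the path, invisibly.
#' @export
writeHelixPDB <- function(ensemble, path) {
  if (is.matrix(ensemble)) ensemble <- list(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(ensemble)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- ensemble[[m]]
    for (i in seq_len(nrow(xyz)))
      writeLines(sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, i, xyz[i, 1L], xyz[i, 2L], xyz[i, 3L]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a CA-only multi-MODEL PDB as a list of coordinate matrices
#'
#' Parses ATOM records with atom name CA, grouped by MODEL; files without
#' MODEL records yield a single conformation.
#'
#' @param path PDB path.
#' @return list of n x 3 coordinate matrices, one per MODEL.
#' @export
readHelixPDB <- function(path) {
  lines <- readLines(path)
  models <- list()
  current <- NULL
  flush_model <- function() {
    if (!is.null(current) && nrow(current) > 0L)
      models[[length(models) + 1L]] <<- current
    current <<- NULL
  }
  for (ln in lines) {
    tag <- substr(ln, 1L, 6L)
    if (tag == "MODEL ") {
      flush_model(); current <- matrix(numeric(0), 0L, 3L)
    } else if (tag == "ENDMDL") {
      flush_model()
    } else if (tag == "ATOM  " && trimws(substr(ln, 13L, 16L)) == "CA") {
      row <- c(as.numeric(substr(ln, 31L, 38L)),
               as.numeric(substr(ln, 39L, 46L)),
               as.numeric(substr(ln, 47L, 54L)))
      if (is.null(current)) current <- matrix(numeric(0), 0L, 3L)
      current <- rbind(current, row)
    }
  }
  flush_model()
  lapply(models, unname)
}
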