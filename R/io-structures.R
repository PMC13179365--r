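# Plain-text structure and trajectory I/O.
#
# Two dialects are supported: multi-model PDB (MODEL/ENDMDL blocks, fixed
# columns) and a long-format trajectory CSV (frame, resnum, resname, atom,
# x, y, z). Binary MD formats are deliberately out of scope.

#' Read a (multi-model) PDB file
#'
#' Parses ATOM and HETATM records; each MODEL/ENDMDL block becomes one
#' frame. Files without MODEL records yield a single frame. CRYST1 box
#' lengths (orthorhombic) are attached as the \code{box} attribute.
#'
#' @param path PDB file path.
#' @return list of \code{pk_frame} (length 1 for single-model files).
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  box <- NULL
  cryst <- grep("^CRYST1", lines, value = TRUE)
  if (length(cryst) >= 1L) {
    box <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                        substr(cryst[1], 25, 33)))
    if (any(is.na(box))) box <- NULL
  }
  frames <- list()
  cur <- character()
  in_model <- FALSE
  flush <- function(buf) {
    if (length(buf) == 0L) return(NULL)
    md_frame(resno = as.integer(substr(buf, 23, 26)),
             resname = trimws(substr(buf, 18, 20)),
             atom = trimws(substr(buf, 13, 16)),
             x = as.numeric(substr(buf, 31, 38)),
             y = as.numeric(substr(buf, 39, 46)),
             z = as.numeric(substr(buf, 47, 54)),
             box = box)
  }
  for (ln in lines) {
    rec <- substr(ln, 1, 6)
    if (startsWith(rec, "MODEL")) {
      in_model <- TRUE
      cur <- character()
    } else if (startsWith(rec, "ENDMDL")) {
      fr <- flush(cur)
      if (!is.null(fr)) frames[[length(frames) + 1L]] <- fr
      cur <- character()
    } else if (rec == "ATOM  " || rec == "HETATM") {
      cur <- c(cur, ln)
    }
  }
  if (length(cur) > 0L) {
    fr <- flush(cur)
    if (!is.null(fr)) frames[[length(frames) + 1L]] <- fr
  }
  if (length(frames) == 0L)
    stop("no ATOM/HETATM records found in ", path, call. = FALSE)
  frames
}

#' Write frames as a multi-model PDB file
#'
#' @param frames a \code{pk_frame} or list of frames.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_pdb <- function(frames, path) {
  if (inherits(frames, "pk_frame") || is.data.frame(frames))
    frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  box <- attr(frames[[1]], "box")
  if (!is.null(box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       box[1], box[2], box[3]), con)
  multi <- length(frames) > 1L
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    is_het <- !(fr$resname %in% c("ALA","ARG","ASN","ASP","CYS","GLN","GLU",
                                  "GLY","HIS","ILE","LEU","LYS","MET","PHE",
                                  "PRO","SER","THR","TRP","TYR","VAL"))
    atom_field <- ifelse(nchar(fr$atom) <= 3L,
                         sprintf(" %-3s", fr$atom), sprintf("%-4s", fr$atom))
    writeLines(sprintf("%-6s%5d %s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                       ifelse(is_het, "HETATM", "ATOM"), seq_len(nrow(fr)),
                       atom_field, fr$resname, fr$resno,
                       fr$x, fr$y, fr$z), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Long format, columns \code{frame, resnum, resname, atom, x, y, z}.
#'
#' @param path CSV path.
#' @return list of \code{pk_frame}.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "resnum", "resname", "atom", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns frame, resnum, resname, atom, x, y, z",
         call. = FALSE)
  lapply(split(df, df$frame), function(d)
    md_frame(d$resnum, d$resname, d$atom, d$x, d$y, d$z))
}

#' Write a trajectory CSV
#' @param frames list of frames.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_trajectory_csv <- function(frames, path) {
  if (inherits(frames, "pk_frame") || is.data.frame(frames))
    frames <- list(frames)
  df <- do.call(rbind, lapply(seq_along(frames), function(k) {
    fr <- frames[[k]]
    data.frame(frame = k, resnum = fr$resno, resname = fr$resname,
               atom = fr$atom, x = fr$x, y = fr$y, z = fr$z)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
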