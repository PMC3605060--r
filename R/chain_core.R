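# Core geometric types (conformation, native structure, trajectory),
# structure/trajectory I/O and Kabsch superposition.

#' Create a conformation (one chain snapshot)
#'
#' A conformation is the universal currency of the package: an ordered set
#' of bead coordinates (one bead per residue, at the C-alpha position),
#' in Angstrom.
#'
#' @param coords numeric N x 3 matrix of bead coordinates (Angstrom).
#' @param chain_id chain label.
#' @param frame_index optional non-negative integer frame index.
#' @return An object of class `conformation`.
#' @export
conformation <- function(coords, chain_id = "A", frame_index = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  if (nrow(coords) < 3L) stop("a conformation needs at least 3 beads")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  d <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                     coords[-nrow(coords), , drop = FALSE])^2))
  if (any(d <= 0)) stop("consecutive beads must be at distinct positions")
  if (!is.null(frame_index)) {
    frame_index <- as.integer(frame_index)
    if (is.na(frame_index) || frame_index < 0L)
      stop("frame_index must be a non-negative integer")
  }
  structure(list(coords = coords, chain_id = as.character(chain_id)[1],
                 frame_index = frame_index),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation> %d beads, chain %s%s\n", nrow(x$coords),
              x$chain_id,
              if (!is.null(x$frame_index))
                sprintf(", frame %d", x$frame_index) else ""))
  invisible(x)
}

n_beads <- function(x) nrow(x$coords)

as_coords <- function(x) {
  if (inherits(x, "conformation")) x$coords
  else if (is.matrix(x)) x
  else stop("expected a conformation or an N x 3 matrix")
}

#' Build a native (reference) structure
#'
#' Derives, from a reference conformation, the native contact set (pairs
#' with C-alpha distance below `contact_cutoff` and sequence separation of
#' at least `min_seq_sep`) and the native smooth contact map used by the
#' collective coordinate.
#'
#' @param reference a [conformation()].
#' @param params a [contact_map_params()].
#' @param contact_cutoff distance (Angstrom) defining a native contact
#'   (default 7.5, the contact-function reference distance).
#' @param regions optional named list of 1-based residue-index vectors
#'   annotating functional regions (e.g. `beta_sheet`, `threading_loop`,
#'   `tail`).  Region annotation is deliberately user-supplied because
#'   author numbering conventions differ between structures.
#' @param sequence optional one-letter amino-acid string of length N.
#' @return An object of class `native_structure` with elements `reference`,
#'   `native_contacts` (two-column matrix, i < j), `native_map`,
#'   `params`, `regions`, `sequence`.
#' @export
native_structure <- function(reference, params = contact_map_params(),
                             contact_cutoff = 7.5, regions = list(),
                             sequence = NULL) {
  stopifnot(inherits(reference, "conformation"))
  x <- reference$coords
  n <- nrow(x)
  dmat <- as.matrix(stats::dist(x))
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  keep <- upper.tri(dmat) & sep >= params$min_seq_sep & dmat <= contact_cutoff
  idx <- which(keep, arr.ind = TRUE)
  native_contacts <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(native_contacts) <- c("i", "j")
  cmap <- contact_value(dmat, params)
  cmap[sep < params$min_seq_sep] <- 0
  diag(cmap) <- 0
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != n) stop("sequence length must equal bead count")
  }
  if (length(regions)) {
    for (nm in names(regions)) {
      r <- regions[[nm]]
      if (any(r < 1L | r > n)) stop("region '", nm, "' out of chain range")
    }
  }
  structure(list(reference = reference, native_contacts = native_contacts,
                 native_map = cmap, params = params,
                 contact_cutoff = contact_cutoff,
                 regions = regions, sequence = sequence),
            class = "native_structure")
}

#' @export
print.native_structure <- function(x, ...) {
  cat(sprintf("<native_structure> %d beads, %d native contacts, regions: %s\n",
              nrow(x$reference$coords), nrow(x$native_contacts),
              if (length(x$regions)) paste(names(x$regions), collapse = ", ")
              else "none"))
  invisible(x)
}

# ---- structure I/O --------------------------------------------------------

#' Read a bead-model structure from a PDB or XYZ file
#'
#' Reads `ATOM` records of the first model (PDB) or the first frame (XYZ)
#' and returns one bead per residue, ordered by residue index.  Only a
#' single chain is read: the first chain encountered unless `chain` is
#' given.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @param atom atom name selecting the bead position (default `"CA"`).
#' @param chain optional chain identifier.
#' @return A [conformation()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz"),
                           atom = "CA", chain = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (format == "xyz") {
    tr <- read_trajectory(path)
    return(get_frame(tr, 1))
  }
  lines <- readLines(path, warn = FALSE)
  # first model only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  rec <- lines[startsWith(lines, "ATOM  ")]
  if (!length(rec)) stop("no ATOM records in ", path)
  f <- function(a, b) trimws(substr(rec, a, b))
  name <- f(13, 16); ch <- f(22, 22); resseq <- as.integer(f(23, 26))
  x <- as.numeric(f(31, 38)); y <- as.numeric(f(39, 46)); z <- as.numeric(f(47, 54))
  chains <- unique(ch)
  if (is.null(chain)) {
    if (length(chains) > 1L)
      stop("multi-chain input; specify `chain` (found: ",
           paste(chains, collapse = ", "), ")")
    chain <- chains[1]
  }
  sel_chain <- ch == chain
  if (!any(sel_chain)) stop("chain '", chain, "' not found")
  residues <- sort(unique(resseq[sel_chain]))
  sel <- sel_chain & name == atom
  got <- resseq[sel]
  missing <- setdiff(residues, got)
  if (length(missing))
    stop("missing-atom: residue(s) ", paste(missing, collapse = ", "),
         " lack atom '", atom, "'")
  ord <- order(resseq[sel])
  coords <- cbind(x[sel], y[sel], z[sel])[ord, , drop = FALSE]
  if (nrow(coords) < 3L) stop("bead selection yields fewer than 3 beads")
  conformation(coords, chain_id = chain)
}

#' Write a conformation as a PDB file (C-alpha trace)
#'
#' @param x a [conformation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "conformation"))
  con <- file(path, "w")
  on.exit(close(con))
  xc <- x$coords
  for (i in seq_len(nrow(xc))) {
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i, substr(x$chain_id, 1, 1), i, xc[i, 1], xc[i, 2], xc[i, 3]), con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- superposition --------------------------------------------------------

# Optimal rotation (Kabsch, via SVD) superposing row-vector set b onto a
# after centering: b %*% kabsch_rotation(a, b) ~ a.
kabsch_rotation <- function(a, b) {
  s <- svd(t(b) %*% a)
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Minimal RMSD between two conformations (Kabsch superposition)
#'
#' @param a,b conformations (or N x 3 matrices) with equal bead count.
#' @param subset optional integer vector (1-based) of beads used both for
#'   the superposition and for the RMSD; default all beads.
#' @return Non-negative RMSD in Angstrom, minimized over rigid motions.
#' @export
kabsch_rmsd <- function(a, b, subset = NULL) {
  pa <- as_coords(a); pb <- as_coords(b)
  if (nrow(pa) != nrow(pb)) stop("conformations differ in bead count")
  if (!is.null(subset)) {
    if (length(subset) < 3L) stop("subset must contain at least 3 beads")
    pa <- pa[subset, , drop = FALSE]; pb <- pb[subset, , drop = FALSE]
  }
  pa <- sweep(pa, 2, colMeans(pa)); pb <- sweep(pb, 2, colMeans(pb))
  rot <- kabsch_rotation(pa, pb)
  sqrt(mean(rowSums((pb %*% rot - pa)^2)))
}

# ---- trajectories ---------------------------------------------------------

#' Create a trajectory object
#'
#' Time-ordered conformations with optional per-frame scalars.  Internally
#' frames are stored as an N x 3 x T array.
#'
#' @param frames list of [conformation()]s (equal bead counts) or an
#'   N x 3 x T array.
#' @param dt time per saved frame (reduced units).
#' @param seed integer seed that generated the trajectory (or `NA`).
#' @param cc_value,bias_energy,potential_energy optional per-frame scalars.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(frames, dt = 1, seed = NA_integer_, cc_value = NULL,
                       bias_energy = NULL, potential_energy = NULL) {
  if (is.list(frames)) {
    if (!length(frames)) stop("a trajectory needs at least one frame")
    ns <- vapply(frames, function(f) nrow(as_coords(f)), integer(1))
    if (length(unique(ns)) != 1L) stop("all frames must have the same bead count")
    arr <- array(0, dim = c(ns[1], 3, length(frames)))
    for (k in seq_along(frames)) arr[, , k] <- as_coords(frames[[k]])
  } else if (is.array(frames) && length(dim(frames)) == 3L) {
    arr <- frames
  } else stop("frames must be a list of conformations or an N x 3 x T array")
  nf <- dim(arr)[3]
  chk <- function(v, nm) {
    if (is.null(v)) return(rep(NA_real_, nf))
    if (length(v) != nf) stop("'", nm, "' must have one value per frame")
    as.double(v)
  }
  stopifnot_scalar(dt, "dt", positive = TRUE)
  structure(list(coords = arr, dt = as.double(dt), seed = seed,
                 cc_value = chk(cc_value, "cc_value"),
                 bias_energy = chk(bias_energy, "bias_energy"),
                 potential_energy = chk(potential_energy, "potential_energy")),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d beads, dt = %g, seed = %s\n",
              n_frames(x), dim(x$coords)[1], x$dt, format(x$seed)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param t a [trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(t) dim(t$coords)[3]

#' Extract one frame of a trajectory as a conformation
#' @param t a [trajectory()].
#' @param k frame index (1-based).
#' @return a [conformation()] with `frame_index = k - 1`.
#' @export
get_frame <- function(t, k) {
  stopifnot(k >= 1, k <= n_frames(t))
  conformation(t$coords[, , k], frame_index = k - 1L)
}

#' Write / read a trajectory (extended-XYZ or multi-model PDB text)
#'
#' The XYZ comment line (or a PDB `REMARK 100` per model) stores the
#' per-frame scalars, so the round trip is lossless at the stated write
#' precision (1e-4 Angstrom for XYZ, 1e-3 for PDB).
#'
#' @param t a [trajectory()].
#' @param path output path.
#' @param format `"auto"` (by extension: `.pdb` is PDB, anything else
#'   XYZ), `"xyz"` or `"pdb"`.
#' @return `path` invisibly (write); a [trajectory()] (read).
#' @export
write_trajectory <- function(t, path, format = c("auto", "xyz", "pdb")) {
  stopifnot(inherits(t, "trajectory"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  if (n_frames(t) < 1L) stop("cannot write an empty trajectory")
  n <- dim(t$coords)[1]
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb") {
    writeLines(sprintf("REMARK  99 knotfold dt=%.12g seed=%s", t$dt,
                       format(t$seed)), con)
    for (k in seq_len(n_frames(t))) {
      writeLines(sprintf("MODEL %8d", k), con)
      writeLines(sprintf("REMARK 100 cc=%.10g bias=%.10g epot=%.10g",
                         t$cc_value[k], t$bias_energy[k],
                         t$potential_energy[k]), con)
      xc <- t$coords[, , k]
      writeLines(sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        seq_len(n), seq_len(n), xc[, 1], xc[, 2], xc[, 3]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    return(invisible(path))
  }
  hdr <- sprintf("# knotfold-xyz dt=%.12g seed=%s", t$dt, format(t$seed))
  writeLines(hdr, con)
  for (k in seq_len(n_frames(t))) {
    writeLines(as.character(n), con)
    writeLines(sprintf("frame=%d cc=%.10g bias=%.10g epot=%.10g",
                       k - 1L, t$cc_value[k], t$bias_energy[k],
                       t$potential_energy[k]), con)
    xc <- t$coords[, , k]
    writeLines(sprintf("CA %.4f %.4f %.4f", xc[, 1], xc[, 2], xc[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (any(startsWith(head(lines, 5), "REMARK  99 knotfold")) ||
      any(startsWith(head(lines, 5), "MODEL")))
    return(read_trajectory_pdb(lines))
  dt <- 1; seed <- NA_integer_
  if (length(lines) && startsWith(lines[1], "# knotfold-xyz")) {
    m <- regmatches(lines[1], regexec("dt=([0-9.eE+-]+) seed=([^ ]+)", lines[1]))[[1]]
    if (length(m) == 3) {
      dt <- as.numeric(m[2])
      seed <- suppressWarnings(as.integer(m[3]))
    }
    lines <- lines[-1]
  }
  frames <- list(); cc <- c(); bias <- c(); epot <- c()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("malformed frame header at line ", i)
    if (i + 1L + n > length(lines)) stop("truncated frame at line ", i)
    meta <- lines[i + 1L]
    getnum <- function(key) {
      m <- regmatches(meta, regexec(paste0(key, "=([0-9.eEnaifNAIF+-]+)"), meta))[[1]]
      if (length(m) == 2) suppressWarnings(as.numeric(m[2])) else NA_real_
    }
    cc <- c(cc, getnum("cc")); bias <- c(bias, getnum("bias"))
    epot <- c(epot, getnum("epot"))
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    nc <- lengths(parts)
    if (any(nc < 4L)) stop("malformed coordinate line in frame starting at line ", i)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (length(frames) && nrow(xyz) != nrow(frames[[1]]))
      stop("inconsistent bead count across frames")
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames in ", path)
  arr <- array(0, dim = c(nrow(frames[[1]]), 3, length(frames)))
  for (k in seq_along(frames)) arr[, , k] <- frames[[k]]
  trajectory(arr, dt = dt, seed = seed, cc_value = cc, bias_energy = bias,
             potential_energy = epot)
}

# multi-model PDB trajectory reader (knotfold dialect: REMARK 99 header,
# REMARK 100 per-model scalars)
read_trajectory_pdb <- function(lines) {
  dt <- 1; seed <- NA_integer_
  hdr <- lines[startsWith(lines, "REMARK  99 knotfold")]
  if (length(hdr)) {
    m <- regmatches(hdr[1], regexec("dt=([0-9.eE+-]+) seed=([^ ]+)", hdr[1]))[[1]]
    if (length(m) == 3) {
      dt <- as.numeric(m[2])
      seed <- suppressWarnings(as.integer(m[3]))
    }
  }
  starts <- which(startsWith(lines, "MODEL"))
  ends <- which(startsWith(lines, "ENDMDL"))
  if (length(starts) != length(ends) || !length(starts))
    stop("malformed multi-model PDB trajectory")
  frames <- list(); cc <- c(); bias <- c(); epot <- c()
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    meta <- block[startsWith(block, "REMARK 100")]
    getnum <- function(key) {
      if (!length(meta)) return(NA_real_)
      m <- regmatches(meta[1],
                      regexec(paste0(key, "=([0-9.eEnaifNAIF+-]+)"), meta[1]))[[1]]
      if (length(m) == 2) suppressWarnings(as.numeric(m[2])) else NA_real_
    }
    cc <- c(cc, getnum("cc")); bias <- c(bias, getnum("bias"))
    epot <- c(epot, getnum("epot"))
    rec <- block[startsWith(block, "ATOM  ")]
    xyz <- cbind(as.numeric(substr(rec, 31, 38)),
                 as.numeric(substr(rec, 39, 46)),
                 as.numeric(substr(rec, 47, 54)))
    if (length(frames) && nrow(xyz) != nrow(frames[[1]]))
      stop("inconsistent bead count across frames")
    frames[[k]] <- xyz
  }
  arr <- array(0, dim = c(nrow(frames[[1]]), 3, length(frames)))
  for (k in seq_along(frames)) arr[, , k] <- frames[[k]]
  trajectory(arr, dt = dt, seed = seed, cc_value = cc, bias_energy = bias,
             potential_energy = epot)
}
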