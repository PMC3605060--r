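# Coarse-grained force field: Go-type native-centric terms plus optional
# non-native quasi-chemical and Debye-screened electrostatic interactions.

# Per-residue charges at neutral pH: Asp/Glu -1, Lys/Arg +1, His 0.
aa_charges <- c(D = -1, E = -1, K = 1, R = 1)

# Kyte-Doolittle hydropathy, used to build a synthetic quasi-chemical
# contact-propensity matrix (a stand-in for statistical-potential tables:
# hydrophobic pairs attract, polar pairs are neutral).
kyte_doolittle <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Synthetic quasi-chemical contact-propensity matrix
#'
#' Builds a symmetric 20 x 20 matrix of pairwise contact energies (kT):
#' `e_ab = -scale * h_a * h_b` with `h` the positive part of the
#' Kyte-Doolittle hydropathy rescaled to `[0, 1]`, so hydrophobic pairs
#' attract and polar/charged pairs are neutral.  This is a synthetic
#' stand-in for published statistical (Miyazawa-Jernigan-type) tables; a
#' custom matrix can be supplied to [ff_params()] instead.
#'
#' @param scale overall well depth scale in kT (default 1).
#' @return 20 x 20 symmetric numeric matrix, dimnames = amino-acid codes.
#' @export
quasichemical_matrix <- function(scale = 1) {
  h <- pmax(kyte_doolittle, 0) / max(kyte_doolittle)
  m <- -scale * outer(h, h)
  dimnames(m) <- list(names(kyte_doolittle), names(kyte_doolittle))
  m
}

#' Read / write a quasi-chemical matrix as TSV
#'
#' The text format is a 20 x 20 tab-separated matrix with amino-acid
#' one-letter codes as header and row names, so custom contact-propensity
#' tables can be supplied to [ff_params()].
#'
#' @param path file path.
#' @param m matrix to write.
#' @return The matrix (read); `path` invisibly (write).
#' @export
read_quasichemical_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("quasi-chemical matrix must be symmetric")
  m
}

#' @rdname read_quasichemical_matrix
#' @export
write_quasichemical_matrix <- function(m, path) {
  utils::write.table(m, path, quote = FALSE, sep = "\t",
                     col.names = NA)
  invisible(path)
}

#' Tunable force-field parameters
#'
#' All energies are in kT at the reference temperature; lengths in
#' Angstrom.
#'
#' @param kb,ka bond / angle spring constants (kT/A^2, kT/rad^2).
#' @param kd1,kd3 1-fold and 3-fold dihedral amplitudes (kT).
#' @param native_eps per-contact native well depth (kT).
#' @param qc_matrix 20 x 20 symmetric quasi-chemical matrix (kT), rows and
#'   columns named by one-letter amino-acid codes.
#' @param qc_range,qc_width range and switching width of the non-native
#'   contact well (Angstrom).
#' @param lB electrostatic prefactor: the Bjerrum length in kT A (~7 A in
#'   water at 300 K).
#' @param lambdaD Debye screening length (Angstrom, default 10).
#' @param sig_ev,eps_ev excluded-volume bead diameter (A) and strength (kT).
#' @return list of class `ff_params`.
#' @export
ff_params <- function(kb = 100, ka = 20, kd1 = 1, kd3 = 0.5,
                      native_eps = 1, qc_matrix = quasichemical_matrix(),
                      qc_range = 6.5, qc_width = 0.5,
                      lB = 7, lambdaD = 10, sig_ev = 4, eps_ev = 1) {
  if (!isTRUE(all.equal(qc_matrix, t(qc_matrix))))
    stop("quasi-chemical matrix must be symmetric")
  stopifnot_scalar(lambdaD, "lambdaD", positive = TRUE)
  structure(list(kb = kb, ka = ka, kd1 = kd1, kd3 = kd3,
                 native_eps = native_eps, qc_matrix = qc_matrix,
                 qc_range = qc_range, qc_width = qc_width, lB = lB,
                 lambdaD = lambdaD, sig_ev = sig_ev, eps_ev = eps_ev),
            class = "ff_params")
}

# internal: dihedral angle of 4 points (used to set native phi0)
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  atan2(sum(m1 * b2) / vnorm(b2), sum(n1 * n2))
}

#' Build a coarse-grained force field from a native structure
#'
#' Bonded terms (harmonic bonds and angles, 1+3-fold cosine dihedrals) are
#' anchored at the native geometry.  Native contacts get 12-10
#' Lennard-Jones-like wells of depth `native_eps` with minima exactly at
#' the native pair distances.  In mode `"with_nonnative"`, non-native pairs
#' additionally feel a quasi-chemical contact well scaled by the propensity
#' matrix and a Debye-screened electrostatic term on charged residues;
#' `"native_only"` zeroes both.  All pairs with sequence separation >= 2
#' outside the native contact set feel excluded-volume repulsion.
#'
#' @param native a [native_structure()].
#' @param sequence one-letter amino-acid string of length N; defaults to
#'   the native's stored sequence, or all-alanine if none.
#' @param mode `"native_only"` or `"with_nonnative"`.
#' @param params a [ff_params()].
#' @return An object of class `forcefield` (opaque; used by [energy()],
#'   [force()] and the samplers).
#' @export
build_forcefield <- function(native, sequence = NULL,
                             mode = c("native_only", "with_nonnative"),
                             params = ff_params()) {
  mode <- match.arg(mode)
  stopifnot(inherits(native, "native_structure"))
  x <- native$reference$coords
  n <- nrow(x)
  sequence <- sequence %||% native$sequence %||% strrep("A", n)
  seqv <- strsplit(toupper(sequence), "")[[1]]
  if (length(seqv) != n) stop("sequence length must equal bead count")
  unknown <- setdiff(seqv, names(kyte_doolittle))
  if (length(unknown))
    stop("unknown amino-acid code: ", paste(unknown, collapse = ", "))
  dvec <- function(i, j) sqrt(rowSums((x[i, , drop = FALSE] - x[j, , drop = FALSE])^2))
  # bonded terms at native geometry
  bi <- seq_len(n - 1); bj <- bi + 1L
  b0 <- dvec(bi, bj)
  ai <- seq_len(n - 2); aj <- ai + 1L; ak <- ai + 2L
  th0 <- vapply(seq_along(ai), function(t) {
    u <- x[ai[t], ] - x[aj[t], ]; v <- x[ak[t], ] - x[aj[t], ]
    acos(max(-1, min(1, sum(u * v) / (vnorm(u) * vnorm(v)))))
  }, numeric(1))
  di <- seq_len(max(0, n - 3)); dj <- di + 1L; dk <- di + 2L; dl <- di + 3L
  ph0 <- vapply(seq_along(di), function(t)
    dihedral_angle(x[di[t], ], x[dj[t], ], x[dk[t], ], x[dl[t], ]), numeric(1))
  # native contact wells at native distances
  nc <- native$native_contacts
  nat_sig <- dvec(nc[, 1], nc[, 2])
  # non-native pair list: all |i-j| >= 2 pairs outside the native set
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  allp <- which(upper.tri(sep) & sep >= 2L, arr.ind = TRUE)
  is_nat <- paste(allp[, 1], allp[, 2]) %in% paste(nc[, 1], nc[, 2])
  pp <- allp[!is_nat, , drop = FALSE]
  pp <- pp[order(pp[, 1], pp[, 2]), , drop = FALSE]
  qcm <- params$qc_matrix
  charges <- ifelse(seqv %in% names(aa_charges), aa_charges[seqv], 0)
  psep <- pp[, 2] - pp[, 1]
  if (mode == "with_nonnative") {
    eqc <- qcm[cbind(seqv[pp[, 1]], seqv[pp[, 2]])]
    qq <- charges[pp[, 1]] * charges[pp[, 2]]
    eqc[psep < 3] <- 0; qq[psep < 3] <- 0 # non-bonded starts at |i-j| >= 3
  } else {
    eqc <- numeric(nrow(pp)); qq <- numeric(nrow(pp))
  }
  spec <- list(
    n = as.integer(n),
    b_i = as.integer(bi - 1L), b_j = as.integer(bj - 1L), b0 = b0,
    a_i = as.integer(ai - 1L), a_j = as.integer(aj - 1L),
    a_k = as.integer(ak - 1L), th0 = th0,
    d_i = as.integer(di - 1L), d_j = as.integer(dj - 1L),
    d_k = as.integer(dk - 1L), d_l = as.integer(dl - 1L), ph0 = ph0,
    kb = params$kb, ka = params$ka, kd1 = params$kd1, kd3 = params$kd3,
    nat_i = as.integer(nc[, 1] - 1L), nat_j = as.integer(nc[, 2] - 1L),
    nat_sig = nat_sig, nat_eps = rep(params$native_eps, nrow(nc)),
    pair_i = as.integer(pp[, 1] - 1L), pair_j = as.integer(pp[, 2] - 1L),
    pair_eqc = as.double(eqc), pair_qq = as.double(qq),
    pair_ev = as.integer(rep(1L, nrow(pp))),
    lB = params$lB, lambdaD = params$lambdaD,
    r_qc = params$qc_range, w_qc = params$qc_width,
    sig_ev = params$sig_ev, eps_ev = params$eps_ev)
  structure(list(spec = spec, mode = mode, params = params,
                 sequence = paste(seqv, collapse = ""),
                 charges = as.numeric(charges), native = native),
            class = "forcefield")
}

#' @export
print.forcefield <- function(x, ...) {
  cat(sprintf("<forcefield> %d beads, mode = %s, %d native wells, %d non-bonded pairs\n",
              x$spec$n, x$mode, length(x$spec$nat_i), length(x$spec$pair_i)))
  invisible(x)
}

#' Energy of a conformation under a force field
#'
#' @param x a [conformation()] (or N x 3 matrix).
#' @param ff a [build_forcefield()] object.
#' @return list of class `energy_breakdown`: components `bonded`, `native`,
#'   `quasichemical`, `electrostatic`, `excluded_volume` and their `total`
#'   (kT units).
#' @export
energy <- function(x, ff) {
  xc <- as_coords(x)
  if (nrow(xc) != ff$spec$n) stop("bead count mismatch")
  r <- cpp_ff_eval(xc, ff$spec, FALSE)
  structure(r[c("bonded", "native", "quasichemical", "electrostatic",
                "excluded_volume", "total")],
            class = "energy_breakdown")
}

#' Force (-gradient of the energy) on each bead
#'
#' @inheritParams energy
#' @return N x 3 matrix of forces in kT/Angstrom.
#' @export
force <- function(x, ff) {
  xc <- as_coords(x)
  if (nrow(xc) != ff$spec$n) stop("bead count mismatch")
  cpp_ff_eval(xc, ff$spec, TRUE)$force
}
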