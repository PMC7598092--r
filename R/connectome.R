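#' Inter-region weights from streamline counts
#'
#' Initializes the connectivity matrix from tractography streamline counts:
#' `W_ij = scale * log(S_ij)` where `S_ij > 0`, and 0 where no streamlines
#' connect the pair. The natural logarithm is the default; `base = "log10"`
#' is available. Counts strictly between 0 and 1 would yield negative weights
#' and are rejected (integer streamline counts can never produce them).
#'
#' @param S Square matrix of non-negative streamline counts, zero diagonal.
#' @param scale Multiplier on the log-count; default 0.1.
#' @param base `"natural"` (default) or `"log10"`.
#' @return Weight matrix of the same shape, zero wherever `S` is zero.
#' @examples
#' init_weights(matrix(c(0, 100, 1, 0), 2, 2))
#' @export
init_weights <- function(S, scale = 0.1, base = c("natural", "log10")) {
  base <- match.arg(base)
  check_square(S, "streamline count matrix")
  if (any(S < 0)) {
    bad <- which(S < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("init_weights: negative streamline count at [%d, %d].",
                  bad[1], bad[2]))
  }
  if (any(S > 0 & S < 1)) {
    bad <- which(S > 0 & S < 1, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "init_weights: count in (0, 1) at [%d, %d] would give a negative weight.",
      bad[1], bad[2]))
  }
  logf <- if (base == "natural") log else log10
  W <- matrix(0, nrow(S), ncol(S))
  pos <- S > 0
  W[pos] <- scale * logf(S[pos])
  diag(W) <- 0
  W
}

#' Conduction delays from fiber lengths
#'
#' Converts fiber trajectory lengths (mm) into conduction delays (ms) at a
#' fixed propagation speed. The default 7 m/s equals 7 mm/ms, so
#' `D_ij = L_ij / 7`.
#'
#' @param L Square matrix of fiber lengths in mm, non-negative.
#' @param v Propagation speed in m/s (> 0); default 7.
#' @return Delay matrix in ms, zero diagonal.
#' @examples
#' compute_delays(matrix(c(0, 70, 7, 0), 2, 2))  # 10 ms and 1 ms
#' @export
compute_delays <- function(L, v = 7) {
  check_square(L, "length matrix")
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
    abort("compute_delays: propagation speed v must be a single number > 0.")
  }
  if (any(L < 0)) abort("compute_delays: lengths must be non-negative.")
  D <- L / v  # v in m/s == mm/ms, L in mm -> D in ms
  diag(D) <- 0
  D
}

#' Assemble and validate a connectome
#'
#' Bundles streamline counts `S`, fiber lengths `L`, derived weights `W` and
#' delays `D` into one validated object. Diagonals are forced to zero (self
#' influence is the internal weight `w1`, not an external connection), `W`
#' must vanish exactly where `S` does, and every connected pair must have a
#' strictly positive delay.
#'
#' @param S,L Streamline count and length matrices (same square shape).
#' @param W,D Optional precomputed weight/delay matrices; derived via
#'   [init_weights()] and [compute_delays()] when omitted.
#' @param v Propagation speed (m/s) used when deriving `D`.
#' @param weight_scale,log_base Passed to [init_weights()] when deriving `W`.
#' @param labels Optional character vector of region labels.
#' @return An object of class `connectome` with fields `n, S, L, W, D, labels`.
#' @export
connectome <- function(S, L, W = NULL, D = NULL, v = 7,
                       weight_scale = 0.1, log_base = "natural",
                       labels = NULL) {
  check_square(S, "streamline count matrix")
  check_square(L, "length matrix")
  if (!all(dim(S) == dim(L))) abort("connectome: S and L must have equal shape.")
  n <- nrow(S)
  if (any(diag(S) != 0) || any(diag(L) != 0)) {
    warn("connectome: nonzero diagonal entries forced to zero.")
    diag(S) <- 0; diag(L) <- 0
  }
  if (is.null(W)) W <- init_weights(S, scale = weight_scale, base = log_base)
  if (is.null(D)) D <- compute_delays(L, v = v)
  if (!all(dim(W) == dim(S)) || !all(dim(D) == dim(S))) {
    abort("connectome: all matrices must have the same shape.")
  }
  diag(W) <- 0; diag(D) <- 0
  if (any(W[S == 0] != 0)) abort("connectome: W must be zero wherever S is zero.")
  if (any(W < 0)) abort("connectome: weights must be non-negative.")
  if (any(W > 0 & D <= 0)) {
    bad <- which(W > 0 & D <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf("connectome: connected pair [%d, %d] has non-positive delay.",
                  bad[1], bad[2]))
  }
  if (!is.null(labels) && length(labels) != n) {
    abort("connectome: labels must have one entry per region.")
  }
  structure(list(n = n, S = S, L = L, W = W, D = D, labels = labels),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  ncon <- sum(x$W != 0)
  cat(sprintf("<connectome> %d regions, %d directed connections (density %.3f)\n",
              x$n, ncon, ncon / max(1, x$n * (x$n - 1))))
  if (ncon > 0) {
    cat(sprintf("  weights in [%.4g, %.4g], delays in [%.4g, %.4g] ms\n",
                min(x$W[x$W > 0]), max(x$W), min(x$D[x$W > 0]), max(x$D)))
  }
  invisible(x)
}

#' Synthetic connectome generator
#'
#' Emulates a DTI-derived structural connectome without any imaging data:
#' each ordered region pair is connected independently with probability `p`
#' (default 0.2, the empirical inter-region connection density used for the
#' biologically realistic network family), connected pairs draw an integer
#' streamline count from `count_law` (default `2 + Geometric`, mean about 50,
#' minimum 2) and a fiber length uniform over `length_range` (default 20-150
#' mm). Weights and delays follow via [init_weights()] and
#' [compute_delays()]. The same seed reproduces the connectome exactly.
#'
#' @param n Number of regions (default 82, the whole-brain parcellation size).
#' @param p Connection probability in \[0, 1\] (default 0.2).
#' @param seed Optional integer seed; when given, the caller's RNG state is
#'   left untouched.
#' @param length_range Numeric length-2 vector, fiber length bounds in mm.
#' @param count_law Function `m -> integer vector of m counts >= 1`.
#' @param v Propagation speed in m/s.
#' @return A [connectome()].
#' @examples
#' con <- synthetic_connectome(n = 10, p = 0.2, seed = 1)
#' sum(con$W != 0)
#' @export
synthetic_connectome <- function(n = 82, p = 0.2, seed = NULL,
                                 length_range = c(20, 150),
                                 count_law = NULL, v = 7) {
  if (!is.numeric(n) || n < 1) abort("synthetic_connectome: n must be >= 1.")
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    abort("synthetic_connectome: p must lie in [0, 1].")
  }
  n <- as.integer(n)
  if (is.null(count_law)) {
    count_law <- function(m) 2L + rgeom(m, prob = 1 / 49)  # mean ~ 50, min 2
  }
  gen <- function() {
    S <- matrix(0, n, n)
    L <- matrix(0, n, n)
    off <- which(row(S) != col(S))
    linked <- off[runif(length(off)) < p]
    m <- length(linked)
    if (m > 0) {
      cnt <- count_law(m)
      if (any(cnt < 1)) abort("synthetic_connectome: count_law returned counts < 1.")
      S[linked] <- cnt
      L[linked] <- runif(m, length_range[1], length_range[2])
    }
    connectome(S, L, v = v)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Expected total number of connections of the synthetic family
#'
#' Each region carries 7 internal connections (the weights w1..w7 of its
#' three-population circuit); external directed connections appear with
#' probability `p` among the `n(n-1)` ordered pairs. The expected total is
#' `7 n + p n (n-1)`, rounded to the nearest integer.
#'
#' @param n Number of regions (>= 1).
#' @param p Connection probability in \[0, 1\].
#' @return Expected edge count (integer-valued numeric).
#' @examples
#' count_edges(100, 0.2)  # 2680
#' @export
count_edges <- function(n, p) {
  if (any(n < 1)) abort("count_edges: n must be >= 1.")
  if (any(p < 0 | p > 1)) abort("count_edges: p must lie in [0, 1].")
  round(7 * n + p * n * (n - 1))
}

#' Read a connectome from matrix files
#'
#' Reads header-less square numeric matrices of streamline counts and fiber
#' lengths (comma- or tab-separated, sniffed from the first line) and builds
#' a validated [connectome()]. Nonzero diagonals are zeroed with a warning;
#' non-square, shape-mismatched, non-numeric or negative input is rejected
#' with the offending cell named.
#'
#' @param streamlines_path,lengths_path Paths to the two matrix files.
#' @param labels_path Optional JSON file holding an array of region labels.
#' @inheritParams connectome
#' @return A [connectome()].
#' @seealso [write_connectome()]
#' @export
read_connectome <- function(streamlines_path, lengths_path,
                            labels_path = NULL, v = 7,
                            weight_scale = 0.1, log_base = "natural") {
  S <- read_matrix_file(streamlines_path, "streamline count matrix")
  L <- read_matrix_file(lengths_path, "length matrix")
  if (!all(dim(S) == dim(L))) {
    abort(sprintf("read_connectome: shape mismatch (%dx%d vs %dx%d).",
                  nrow(S), ncol(S), nrow(L), ncol(L)))
  }
  labels <- if (!is.null(labels_path)) {
    as.character(jsonlite::read_json(labels_path, simplifyVector = TRUE))
  }
  connectome(S, L, v = v, weight_scale = weight_scale, log_base = log_base,
             labels = labels)
}

#' Write a connectome to plain-text matrix files
#'
#' Writes `S.csv` and `L.csv` (header-less CSV, full `%.17g` precision so a
#' write-then-read round trip reproduces every value exactly) and, when
#' labels are present, `labels.json`.
#'
#' @param con A [connectome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_connectome <- function(con, dir) {
  stopifnot(inherits(con, "connectome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_file(con$S, file.path(dir, "S.csv"))
  write_matrix_file(con$L, file.path(dir, "L.csv"))
  if (!is.null(con$labels)) {
    jsonlite::write_json(con$labels, file.path(dir, "labels.json"))
  }
  invisible(dir)
}

# ---- helpers ----------------------------------------------------------------

check_square <- function(M, what) {
  if (!is.matrix(M) || !is.numeric(M)) {
    abort(sprintf("%s must be a numeric matrix.", what))
  }
  if (nrow(M) != ncol(M)) {
    abort(sprintf("%s must be square (got %dx%d).", what, nrow(M), ncol(M)))
  }
  if (any(!is.finite(M))) {
    bad <- which(!is.finite(M), arr.ind = TRUE)[1, ]
    abort(sprintf("%s has a non-finite entry at [%d, %d].", what, bad[1], bad[2]))
  }
  invisible(M)
}

read_matrix_file <- function(path, what) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- tryCatch(
    read.table(path, sep = sep, header = FALSE, colClasses = "numeric"),
    error = function(e) abort(sprintf("%s (%s): non-numeric or malformed input: %s",
                                      what, path, conditionMessage(e))))
  M <- as.matrix(df)
  dimnames(M) <- NULL
  if (nrow(M) != ncol(M)) {
    abort(sprintf("%s (%s) must be square (got %dx%d).", what, path,
                  nrow(M), ncol(M)))
  }
  if (any(M < 0)) {
    bad <- which(M < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("%s (%s): negative value at [%d, %d].", what, path,
                  bad[1], bad[2]))
  }
  M
}

write_matrix_file <- function(M, path) {
  txt <- apply(M, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(txt, path)
  invisible(path)
}
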