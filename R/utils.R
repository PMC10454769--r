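# Shared internal helpers: element handling, seeded RNG scopes, small math.

# Monoisotopic-ish standard atomic weights (Da) for the elements that occur
# in protein/ligand heavy-atom models plus hydrogen.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  NA. = 22.990, K = 39.098, MG = 24.305, ZN = 65.38, FE = 55.845
)

.mass_of <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- .element_masses[key]
  unname(m)
}

# PDB-style element inference from the atom name when columns 77-78 are
# absent: strip leading digits, take the leading alphabetic run; "1HB"-type
# hydrogens and two-letter elements (CL, BR, ...) handled by lookup.
.infer_element <- function(name) {
  nm <- toupper(trimws(name))
  nm <- sub("^[0-9']+", "", nm)
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  ifelse(two %in% c("CL", "BR", "MG", "ZN", "FE", "NA", "SE") &
           !(one %in% c("C", "N", "O", "S", "H") &
               substr(nm, 2, 2) %in% c("A", "B", "G", "D", "E", "Z", "H", "X", "T", "1", "2", "3", "")),
         two, one)
}

# Deterministic sub-seed derivation: one user-facing seed fans out into
# independent, label-addressable substreams (stage names, trajectory ids).
.sub_seed <- function(seed, label) {
  codes <- utf8ToInt(as.character(label))
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h * 1009 + 17) %% 2147483647)
}

# Evaluate code under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# All-pairs Euclidean cross-distance between the rows of A (n x 3) and
# B (m x 3); vectorized, used by the secondary-structure stage.
.cdist <- function(A, B) {
  a2 <- rowSums(A * A)
  b2 <- rowSums(B * B)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# xyz frame matrix (F x 3A, bio3d layout) -> coordinates of frame f (A x 3)
.frame_coords <- function(xyz, f) {
  matrix(xyz[f, ], ncol = 3, byrow = TRUE)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
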