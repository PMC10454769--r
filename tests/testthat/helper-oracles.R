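# Independent oracles and toy-model builders shared across the test files.
# Oracles are deliberately naive (O(N^2) scans, closed forms, quaternion
# algebra) and never call the code paths they check.

# Build a structure_model from a list of residues; each element is a list
# with fields resid, chain, resname, and a named list of atoms
# (name -> c(x, y, z)).  All atoms default to carbon.
toy_model <- function(residues, frames = NULL, condition = "toy") {
  atoms <- list(); coords <- list()
  for (r in residues) {
    nm <- names(r$atoms)
    el <- ifelse(substr(nm, 1, 1) %in% c("N", "O", "S"), substr(nm, 1, 1), "C")
    atoms[[length(atoms) + 1]] <- data.frame(
      name = nm, element = el, mass = ifelse(el == "N", 14.007,
        ifelse(el == "O", 15.999, ifelse(el == "S", 32.06, 12.011))),
      resid = r$resid, resname = r$resname %||% "ALA",
      chain = r$chain %||% "A")
    coords[[length(coords) + 1]] <- do.call(rbind, r$atoms)
  }
  atoms <- do.call(rbind, atoms)
  x0 <- as.vector(t(do.call(rbind, coords)))
  xyz <- if (is.null(frames)) matrix(x0, nrow = 1) else frames
  structure_model(atoms, xyz, condition = condition)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-atom-per-residue helper: coords is an n x 3 matrix
point_residues <- function(coords, chain = "A", name = "CA", resname = "ALA",
                           start = 1L) {
  lapply(seq_len(nrow(coords)), function(i)
    list(resid = start + i - 1L, chain = chain, resname = resname,
         atoms = setNames(list(coords[i, ]), name)))
}

# O(N^2) all-atom-pair contact oracle over the heavy atoms of a frame
brute_contacts <- function(model, frame, cutoff) {
  at <- model$atoms
  co <- matrix(model$xyz[frame, ], ncol = 3, byrow = TRUE)
  heavy <- which(toupper(at$element) != "H")
  key <- paste(at$chain, at$resid, sep = ":")
  res <- unique(key[heavy])
  out <- character(0)
  for (a in seq_along(res)) {
    ia <- heavy[key[heavy] == res[a]]
    for (b in seq_along(res)) {
      if (b <= a) next
      ib <- heavy[key[heavy] == res[b]]
      hit <- FALSE
      for (x in ia) for (y in ib) {
        if (sqrt(sum((co[x, ] - co[y, ])^2)) <= cutoff) { hit <- TRUE; break }
      }
      if (hit) out <- c(out, paste(res[a], res[b]))
    }
  }
  sort(out)
}

# Horn's quaternion absolute-orientation method: independent superposition
# oracle returning the optimal proper rotation
quaternion_rotation <- function(mobile, reference) {
  M <- sweep(mobile, 2, colMeans(mobile))
  R0 <- sweep(reference, 2, colMeans(reference))
  S <- t(M) %*% R0
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2
  ), 3, 3, byrow = TRUE)
}

# random symmetric weighted adjacency with a connected backbone
random_weighted_graph <- function(n, p = 0.15) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- runif(1, 0.2, 1)
  extra <- which(upper.tri(W) & matrix(runif(n * n) < p, n, n), arr.ind = TRUE)
  for (k in seq_len(nrow(extra))) {
    w <- runif(1, 0.05, 1)
    W[extra[k, 1], extra[k, 2]] <- W[extra[k, 2], extra[k, 1]] <- w
  }
  W
}

# residue_graph object directly from an adjacency matrix (node i = resid i)
graph_from_adjacency <- function(W) {
  n <- nrow(W)
  pr <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  tab <- data.frame(res_i = pr[, 1], res_j = pr[, 2],
                    chain_i = "A", chain_j = "A", freq = W[pr])
  # zero-frequency self pairs anchor isolated nodes in the node table
  build_graph(rbind(tab,
                    data.frame(res_i = seq_len(n), res_j = seq_len(n),
                               chain_i = "A", chain_j = "A", freq = 0)),
              min_sequence_gap = 0L)
}

# small ensemble spec used by several files: quick to generate
quick_spec <- function(frames_per_trajectory = 60L, ...) {
  synthetic_spec(n_trajectories = 1L,
                 frames_per_trajectory = frames_per_trajectory, ...)
}
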