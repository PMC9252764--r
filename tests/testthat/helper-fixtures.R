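# Shared test helpers: tiny profiles and structures built in code.

aa20 <- ddgpred::AA_STANDARD

# one-hot profile for a sequence (thin alias to keep tests terse)
onehot <- function(sequence) single_sequence_profile(sequence)

# profile with arbitrary frequency columns: `cols` is a list of named
# numeric vectors (one per position), each summing to 1
profile_from_cols <- function(cols, query = NULL) {
  L <- length(cols)
  freqs <- matrix(0, 20L, L, dimnames = list(aa20, NULL))
  for (j in seq_len(L)) freqs[names(cols[[j]]), j] <- cols[[j]]
  if (is.null(query)) query <- vapply(cols, function(f) names(which.max(f)), "")
  structure(list(freqs = freqs, depth = rep(1L, L), query = query,
                 length = L, one_hot = FALSE),
            class = "ddg_profile")
}

# random valid profile (Dirichlet columns), deterministic under the caller's seed
random_profile <- function(L = 8L) {
  cols <- lapply(seq_len(L), function(j) {
    g <- stats::rgamma(20, shape = 0.5)
    stats::setNames(g / sum(g), aa20)
  })
  profile_from_cols(cols)
}

# random single substitution at a position of `profile`
random_variant <- function(profile) {
  pos <- sample.int(profile$length, 1L)
  wt <- profile$query[pos]
  mut <- sample(setdiff(aa20, wt), 1L)
  list(fwd = sprintf("%s%d%s", wt, pos, mut),
       rev = sprintf("%s%d%s", mut, pos, wt))
}

# write a fixture structure to a temp PDB and read it back
read_fixture_structure <- function(spec, chain = "A") {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  make_structure(spec, path, chain = chain)
  read_structure(path, chain)
}

# brute-force reference for the contact environment: triple loop over
# residues and atom pairs, independent of the package's vectorized path
brute_force_neighbors <- function(model, site_key, radius) {
  atoms <- model$atoms
  keys <- unique(model$residues$key)
  site_xyz <- as.matrix(atoms[atoms$key == site_key, c("x", "y", "z")])
  found <- character(0)
  for (k in setdiff(keys, site_key)) {
    xyz <- as.matrix(atoms[atoms$key == k, c("x", "y", "z")])
    hit <- FALSE
    for (i in seq_len(nrow(site_xyz))) {
      for (j in seq_len(nrow(xyz))) {
        if (sqrt(sum((site_xyz[i, ] - xyz[j, ])^2)) <= radius) hit <- TRUE
      }
    }
    if (hit) found <- c(found, k)
  }
  found
}
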