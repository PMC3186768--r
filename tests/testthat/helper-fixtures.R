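# shared generators and brute-force oracles for the property tests

# random connected molecular graph (random spanning tree plus a few extra
# edges); graphs need not be chemically sensible, only structurally valid
random_mol_graph <- function(n, seed,
                             elements = c("C", "C", "C", "N", "O", "S"),
                             orders = c("single", "single", "double",
                                        "aromatic")) {
  set.seed(seed)
  el <- sample(elements, n, replace = TRUE)
  if (n == 1L) return(mol_graph(el, 0L, NULL, source_id = paste0("rand", seed)))
  j <- 2:n
  i <- vapply(j, function(k) sample.int(k - 1L, 1L), integer(1))
  bonds <- data.frame(i = i, j = j,
                      order = sample(orders, n - 1L, replace = TRUE))
  for (try in seq_len(2L)) {                    # a few chords make cycles
    a <- sample.int(n, 1L); b <- sample.int(n, 1L)
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (a != b && !(paste(min(a, b), max(a, b)) %in% key)) {
      bonds <- rbind(bonds, data.frame(i = a, j = b,
                                       order = sample(orders, 1L)))
    }
  }
  mol_graph(el, 0L, bonds, source_id = paste0("rand", seed))
}

# relabel atoms by a permutation: atom k moves to position perm[k]
permute_mol_graph <- function(g, perm) {
  inv <- order(perm)
  mol_graph(g$atoms$element[inv], g$atoms$charge[inv],
            data.frame(i = perm[g$bonds$i], j = perm[g$bonds$j],
                       order = g$bonds$order),
            source_id = paste0(g$source_id, "-perm"))
}

# brute-force all-pairs shortest path (Floyd-Warshall) oracle
fw_distances <- function(g) {
  n <- n_atoms(g)
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (k in seq_len(n_bonds(g))) {
    d[g$bonds$i[k], g$bonds$j[k]] <- 1
    d[g$bonds$j[k], g$bonds$i[k]] <- 1
  }
  for (m in seq_len(n)) for (a in seq_len(n)) for (b in seq_len(n)) {
    if (d[a, m] + d[m, b] < d[a, b]) d[a, b] <- d[a, m] + d[m, b]
  }
  d[is.infinite(d)] <- NA
  d
}

# study-shaped synthetic dataset: 99 substrates / 98 non-substrates
study_shaped_dataset <- function(seed, separation = 3, n_informative = 2,
                                 n_noise = 10, n_duplicates = 0) {
  ds <- synthetic_feature_dataset(n_per_class = 99,
                                  n_informative = n_informative,
                                  n_noise = n_noise, separation = separation,
                                  n_duplicates = n_duplicates, seed = seed)
  keep <- 1:197                       # drop one non-substrate: 99 / 98
  labeled_dataset(ds$ids[keep], ds$labels[keep], ds$X[keep, , drop = FALSE])
}

# coarse protocol configuration used for synthetic benchmark runs
protocol_cfg <- function(seed) {
  svm_config(C_grid = 2^seq(-1, 5, by = 2), gamma_grid = 2^seq(-7, -1, by = 2),
             folds = 3, seed = seed)
}
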