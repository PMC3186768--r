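#' Toy molecules with hand-computed descriptor values
#'
#' A fixed list of small named molecules whose in-scope descriptor values
#' can be verified by hand; each entry carries the SMILES, the expected
#' values (written as explicit arithmetic over the packaged property table,
#' so their provenance is the formula itself) and a note on how each number
#' arises.
#'
#' @return Named list of entries with \code{smiles}, \code{expected}
#'   (named list of descriptor operation results) and \code{note}.
#' @export
toy_molecules <- function() {
  p <- atom_property_table()
  w_O_mass <- p["O", "mass"] / p["C", "mass"]
  list(
    ethane = list(
      smiles = "CC",
      expected = list(
        n_atoms = 2, n_bonds = 1,
        ATS1m = 1,                       # single C-C pair, weight 1*1
        BEL1m = 0.89,                    # eigen of [[1, .11], [.11, 1]]
        BEH1m = 1.11,
        ESpm02x = 0,                     # one bond: edge matrix [[0]]
        ESpm02d = 0),                    # homonuclear bond dipole 0
      note = "2x2 Burden matrix with terminal augmentation 0.1*1 + 0.01"),
    propane = list(
      smiles = "CCC",
      expected = list(
        n_atoms = 3, n_bonds = 2,
        d13 = 2,                         # two-bond path end to end
        EEig1x = 2,                      # eigenvalues of [[1,1],[1,1]]: 2, 0
        ESpm02x = 4),                    # trace of [[2,2],[2,2]]
      note = "edge-degree edge adjacency [[1,1],[1,1]]"),
    ethanol = list(
      smiles = "CCO",
      expected = list(
        n_atoms = 3, n_bonds = 2,
        ATS1m = 1 + w_O_mass,            # C-C pair + C-O pair (1 * m_O/m_C)
        mass_weights = c(1, 1, w_O_mass)),
      note = "lag-1 pairs are the two bonds; O weight is 15.999/12.011"),
    benzene = list(
      smiles = "c1ccccc1",
      expected = list(
        n_atoms = 6, n_bonds = 6,
        max_distance = 3,                # para positions on the 6-cycle
        ATS1m = 6),                      # six C-C pairs at distance 1
      note = "aromatic order preserved; all atoms carbon so weights are 1"),
    acetate_salt = list(
      smiles = "[Na+].CC(=O)[O-]",
      expected = list(
        n_atoms = 4, n_bonds = 3),       # acetate fragment kept, Na+ dropped
      note = "largest heavy-atom fragment retained before element checks")
  )
}

#' Synthetic labeled feature dataset
#'
#' Two multivariate-Gaussian classes for selection/training tests:
#' informative features have unit within-class standard deviation and class
#' means separated by \code{separation} (in units of that sd); noise
#' features share one N(0, 1) distribution in both classes; optional
#' near-duplicate columns (correlation above 0.95 with an informative
#' feature) exercise the correlation pruning. Fully determined by
#' \code{seed}.
#'
#' @param n_per_class Compounds per class (substrates = class 1 first).
#' @param n_informative Number of class-separating features
#'   (\code{inf1}, \code{inf2}, ...).
#' @param n_noise Number of uninformative features (\code{noise1}, ...).
#' @param separation Class-mean separation in within-class sd units.
#' @param n_duplicates Number of near-duplicate columns (\code{dup1}, ...),
#'   copies of the informative features plus N(0, 0.15^2) jitter.
#' @param seed Integer seed.
#' @return A \code{labeled_dataset} with the feature matrix attached.
#' @export
synthetic_feature_dataset <- function(n_per_class = 100, n_informative = 2,
                                      n_noise = 20, separation = 3,
                                      n_duplicates = 0, seed = 1) {
  stopifnot(n_per_class >= 2, n_informative >= 0, n_noise >= 0,
            separation >= 0, n_duplicates >= 0)
  set.seed(seed)
  n <- 2L * n_per_class
  y <- rep(c(1L, 0L), each = n_per_class)
  cols <- list()
  for (k in seq_len(n_informative)) {
    cols[[paste0("inf", k)]] <- stats::rnorm(n, mean = separation * (y == 1L))
  }
  for (k in seq_len(n_noise)) {
    cols[[paste0("noise", k)]] <- stats::rnorm(n)
  }
  X <- do.call(cbind, cols)
  if (n_duplicates > 0) {
    if (n_informative == 0) stop("duplicates require informative features")
    for (k in seq_len(n_duplicates)) {
      src <- ((k - 1L) %% n_informative) + 1L
      X <- cbind(X, X[, paste0("inf", src)] + stats::rnorm(n, sd = 0.15))
      colnames(X)[ncol(X)] <- paste0("dup", k)
    }
  }
  labeled_dataset(sprintf("cmp%04d", seq_len(n)), y, X,
                  provenance = rep("synthetic two-Gaussian generator", n))
}

# fragment vocabulary for the synthetic structure generator; every piece is
# valence-safe when concatenated linearly
.chain_atoms <- c("C", "C", "C", "C", "C", "N", "O", "S")
.terminals <- c("", "", "Cl", "F", "Br", "O", "N")

#' Synthetic compound table
#'
#' A synthetic stand-in for a curated substrate/non-substrate compound
#' table, with the same shape as the study dataset: 99 substrates (class 1)
#' and 98 non-substrates (class 0) by default. Structures are simple
#' generated SMILES (linear hetero-chains, optional benzene ring and
#' carbonyl units); substrates are drawn larger than non-substrates so the
#' two classes genuinely differ in descriptor space. This is synthetic
#' data for exercising the pipeline, not a literature compilation.
#'
#' @param n_substrate,n_nonsubstrate Class sizes.
#' @param seed Integer seed; the packaged fixture uses the default.
#' @return Data frame with columns \code{id}, \code{name}, \code{smiles},
#'   \code{class}, \code{source}.
#' @export
synthetic_compound_table <- function(n_substrate = 99, n_nonsubstrate = 98,
                                     seed = 20117) {
  set.seed(seed)
  gen_smiles <- function(min_len, max_len, ring_prob) {
    len <- sample(min_len:max_len, 1)
    atoms <- c("C", sample(.chain_atoms, max(len - 2L, 0L), replace = TRUE), "C")
    if (stats::runif(1) < 0.4) {
      pos <- sample(seq_along(atoms), 1)
      atoms[pos] <- "C(=O)"              # carbonyl unit keeps valence safe
    }
    s <- paste(atoms, collapse = "")
    if (stats::runif(1) < ring_prob) s <- paste0("c1ccccc1", s)
    term <- sample(.terminals, 1)
    paste0(s, term)
  }
  sub <- vapply(seq_len(n_substrate), function(k) gen_smiles(8, 20, 0.7),
                character(1))
  non <- vapply(seq_len(n_nonsubstrate), function(k) gen_smiles(2, 10, 0.25),
                character(1))
  data.frame(
    id = c(sprintf("S%03d", seq_len(n_substrate)),
           sprintf("N%03d", seq_len(n_nonsubstrate))),
    name = c(sprintf("synthetic-substrate-%03d", seq_len(n_substrate)),
             sprintf("synthetic-nonsubstrate-%03d", seq_len(n_nonsubstrate))),
    smiles = c(sub, non),
    class = rep(c(1L, 0L), c(n_substrate, n_nonsubstrate)),
    source = "synthetic structure generator",
    stringsAsFactors = FALSE)
}

#' Write a compound table
#'
#' Tab-separated with a header row — the same schema the loader and the
#' command-line tools consume.
#'
#' @param tab Data frame with columns id, name, smiles, class (and
#'   optionally source).
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_compound_table <- function(tab, file) {
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Path of the packaged synthetic compound table
#'
#' The vendored fixture produced by \code{\link{synthetic_compound_table}}
#' with its default arguments (99 substrates, 98 non-substrates).
#'
#' @return File path.
#' @export
packaged_compound_table <- function() {
  system.file("extdata", "synthetic_compounds_s1.tsv", package = "pgpsub",
              mustWork = TRUE)
}
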