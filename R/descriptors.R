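#' Broto-Moreau topological autocorrelation (ATS)
#'
#' Sum over unordered atom pairs \{i, j\} at topological distance exactly
#' \code{lag} of the product of carbon-scaled atomic property weights
#' \eqn{w_i w_j}. Returns 0 when no pair sits at that distance (including
#' one-atom molecules).
#'
#' @param g A \code{mol_graph}.
#' @param lag Positive integer topological distance.
#' @param property Atomic property used for the weights (see
#'   \code{\link{atom_weights}}).
#' @param properties Atom property table.
#' @return A single numeric value.
#' @examples
#' ats_autocorrelation(parse_molecule("CC"), 1, "mass")   # 1: one C-C pair
#' @export
ats_autocorrelation <- function(g, lag, property = "mass",
                                properties = atom_property_table()) {
  stopifnot(lag >= 1)
  w <- atom_weights(g, property, properties)
  d <- topological_distance_matrix(g)
  pairs <- which(upper.tri(d) & !is.na(d) & d == lag, arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(0)
  sum(w[pairs[, 1]] * w[pairs[, 2]])
}

#' Burden matrix
#'
#' The modified adjacency matrix behind the BEL/BEH eigenvalue descriptors:
#' diagonal entry i is the atom's carbon-scaled property weight; for bonded
#' pairs the off-diagonal entry is 0.1 times the conventional bond order
#' (1, 2, 3, or 1.5 for aromatic), plus 0.01 when either atom is terminal
#' (degree 1); all non-bonded pairs get 0.001.
#'
#' @inheritParams ats_autocorrelation
#' @return A symmetric numeric matrix (atoms x atoms).
#' @export
burden_matrix <- function(g, property = "mass",
                          properties = atom_property_table()) {
  n <- n_atoms(g)
  w <- atom_weights(g, property, properties)
  B <- matrix(0.001, n, n)
  diag(B) <- w
  if (n_bonds(g) > 0L) {
    deg <- tabulate(c(g$bonds$i, g$bonds$j), nbins = n)
    for (k in seq_len(n_bonds(g))) {
      i <- g$bonds$i[k]; j <- g$bonds$j[k]
      v <- 0.1 * .bond_order_value[[g$bonds$order[k]]]
      if (deg[i] == 1L || deg[j] == 1L) v <- v + 0.01
      B[i, j] <- v; B[j, i] <- v
    }
  }
  B
}

#' Burden matrix eigenvalue descriptors (BEL / BEH)
#'
#' The n-th smallest (\code{which = "lowest"}, BEL series) or n-th largest
#' (\code{"highest"}, BEH series) eigenvalue of the property-weighted Burden
#' matrix. Molecules with fewer than \code{n} atoms cannot supply the
#' eigenvalue; the padding policy returns 0 with the \code{"pad"} attribute
#' set, so small molecules flow through a descriptor pipeline.
#'
#' @inheritParams ats_autocorrelation
#' @param n Eigenvalue index (1-based).
#' @param which \code{"lowest"} or \code{"highest"}.
#' @return Numeric value with logical attribute \code{"pad"}.
#' @export
burden_eigenvalue <- function(g, property = "mass", n = 1,
                              which = c("lowest", "highest"),
                              properties = atom_property_table()) {
  stopifnot(n >= 1)
  which <- match.arg(which)
  if (n_atoms(g) < n) return(structure(0, pad = TRUE))
  ev <- eigen(burden_matrix(g, property, properties), symmetric = TRUE,
              only.values = TRUE)$values          # decreasing order
  val <- if (which == "lowest") sort(ev)[n] else ev[n]
  structure(val, pad = FALSE)
}

#' Weighted edge-adjacency matrix
#'
#' Bonds-by-bonds matrix: off-diagonal entry (e, f) is 1 when bonds e and f
#' share an atom, else 0; the diagonal carries the bond weight — either the
#' edge degree (number of adjacent bonds) or the bond dipole moment from the
#' packaged bond dipole table.
#'
#' @param g A \code{mol_graph} with at least one bond.
#' @param weighting \code{"edge_degree"} or \code{"bond_dipole"}.
#' @param dipoles Bond dipole table (see \code{\link{bond_dipole_table}}).
#' @return A symmetric numeric matrix (bonds x bonds).
#' @export
edge_adjacency_matrix <- function(g, weighting = c("edge_degree", "bond_dipole"),
                                  dipoles = bond_dipole_table()) {
  weighting <- match.arg(weighting)
  m <- n_bonds(g)
  if (m < 1L) stop("molecule '", g$source_id, "' has no bonds")
  E <- matrix(0, m, m)
  for (e in seq_len(m - 1L)) {
    for (f in seq(e + 1L, m)) {
      share <- length(intersect(c(g$bonds$i[e], g$bonds$j[e]),
                                c(g$bonds$i[f], g$bonds$j[f]))) > 0L
      if (share) { E[e, f] <- 1; E[f, e] <- 1 }
    }
  }
  diag(E) <- if (weighting == "edge_degree") {
    rowSums(E)
  } else {
    vapply(seq_len(m), function(e) {
      .bond_dipole(g$atoms$element[g$bonds$i[e]],
                   g$atoms$element[g$bonds$j[e]],
                   g$bonds$order[e], dipoles)
    }, numeric(1))
  }
  E
}

#' Edge-adjacency eigenvalue descriptors (EEig)
#'
#' The index-th largest eigenvalue of the weighted edge-adjacency matrix;
#' pads with 0 (and the \code{"pad"} attribute) when the molecule has fewer
#' bonds than \code{index}.
#'
#' @inheritParams edge_adjacency_matrix
#' @param index Eigenvalue index (1-based, largest first).
#' @return Numeric value with logical attribute \code{"pad"}.
#' @export
edge_eigenvalue <- function(g, weighting = "edge_degree", index = 1,
                            dipoles = bond_dipole_table()) {
  stopifnot(index >= 1)
  if (n_bonds(g) < index) return(structure(0, pad = TRUE))
  ev <- eigen(edge_adjacency_matrix(g, weighting, dipoles), symmetric = TRUE,
              only.values = TRUE)$values
  structure(ev[index], pad = FALSE)
}

#' Edge-adjacency spectral moments (ESpm)
#'
#' Trace of the weighted edge-adjacency matrix raised to \code{order}; the
#' order-0 moment is the bond count. A bond-less molecule pads with 0.
#'
#' @inheritParams edge_adjacency_matrix
#' @param order Non-negative integer power.
#' @return Numeric value with logical attribute \code{"pad"}.
#' @export
edge_spectral_moment <- function(g, weighting = "edge_degree", order = 2,
                                 dipoles = bond_dipole_table()) {
  stopifnot(order >= 0)
  if (n_bonds(g) < 1L) return(structure(0, pad = TRUE))
  E <- edge_adjacency_matrix(g, weighting, dipoles)
  P <- diag(nrow(E))
  for (k in seq_len(order)) P <- P %*% E
  structure(sum(diag(P)), pad = FALSE)
}

# ---------------------------------------------------------------------------
# descriptor name grammar: ATS<lag><w>, BEL<n><w>, BEH<n><w> with atomic
# weight w in {m, v, e, p}; EEig<n><w>, ESpm<k><w> with edge weight w in
# {x = edge degree, d = bond dipole}. Numeric parts may carry leading zeros
# (ESpm02d).
# ---------------------------------------------------------------------------

.atomic_weight_codes <- c(m = "mass", v = "volume", e = "electronegativity",
                          p = "polarizability")
.edge_weight_codes <- c(x = "edge_degree", d = "bond_dipole")

.parse_descriptor_name <- function(name) {
  m <- regmatches(name, regexec("^(ATS|BEL|BEH)([0-9]+)([mvep])$", name))[[1]]
  if (length(m)) {
    return(list(family = m[2], index = as.integer(m[3]),
                weight = .atomic_weight_codes[[m[4]]]))
  }
  m <- regmatches(name, regexec("^(EEig|ESpm)([0-9]+)([xd])$", name))[[1]]
  if (length(m)) {
    return(list(family = m[2], index = as.integer(m[3]),
                weight = .edge_weight_codes[[m[4]]]))
  }
  stop("unknown descriptor name '", name, "'; the grammar is ",
       "ATS<lag><w>, BEL<n><w>, BEH<n><w> (w in m/v/e/p), ",
       "EEig<n><w>, ESpm<k><w> (w in x/d)")
}

#' Names of the final-model descriptors
#'
#' The six 2D descriptors of the selected substrate-classification model:
#' ATS1m (mass-weighted lag-1 autocorrelation), EEig12x (12th eigenvalue of
#' the edge-degree-weighted edge-adjacency matrix), ESpm02d (order-2 spectral
#' moment, dipole weighting), and the 6th-lowest Burden eigenvalues weighted
#' by van der Waals volume (BELv6), Sanderson electronegativity (BELe6) and
#' polarizability (BELp6).
#'
#' @return Character vector of six descriptor names.
#' @export
final_model_descriptors <- function() {
  c("ATS1m", "EEig12x", "ESpm02d", "BELv6", "BELe6", "BELp6")
}

# Dragon-style names put the weight letter before the index for the Burden
# family (BELv6), after it for ATS/EEig/ESpm (ATS1m, EEig12x). Normalize to
# the grammar's <family><index><weight> form.
.normalize_descriptor_name <- function(name) {
  m <- regmatches(name, regexec("^(BEL|BEH)([mvep])([0-9]+)$", name))[[1]]
  if (length(m)) return(paste0(m[2], m[4], m[3]))
  name
}

#' Compute a block of named descriptors
#'
#' Evaluates each name in \code{spec} (default: the final model's six
#' descriptors) on one molecular graph. Values whose eigenvalue index or
#' bond requirement exceeds what the molecule offers are padded with 0 and
#' flagged.
#'
#' @param g A \code{mol_graph}.
#' @param spec Character vector of descriptor names in the registered
#'   grammar; Dragon-style Burden names (\code{BELv6}) are accepted.
#' @param properties Atom property table.
#' @param dipoles Bond dipole table.
#' @return Named numeric vector with a logical \code{"pad"} attribute of the
#'   same length marking padded entries.
#' @export
compute_descriptor_block <- function(g, spec = final_model_descriptors(),
                                     properties = atom_property_table(),
                                     dipoles = bond_dipole_table()) {
  vals <- numeric(length(spec))
  pads <- logical(length(spec))
  for (k in seq_along(spec)) {
    p <- .parse_descriptor_name(.normalize_descriptor_name(spec[k]))
    v <- switch(p$family,
      ATS = ats_autocorrelation(g, p$index, p$weight, properties),
      BEL = burden_eigenvalue(g, p$weight, p$index, "lowest", properties),
      BEH = burden_eigenvalue(g, p$weight, p$index, "highest", properties),
      EEig = edge_eigenvalue(g, p$weight, p$index, dipoles),
      ESpm = edge_spectral_moment(g, p$weight, p$index, dipoles))
    vals[k] <- as.numeric(v)
    pads[k] <- isTRUE(attr(v, "pad"))
  }
  if (any(!is.finite(vals))) {
    stop("non-finite descriptor value for molecule '", g$source_id, "'")
  }
  structure(stats::setNames(vals, spec), pad = pads)
}

#' Descriptor matrix for a set of molecules
#'
#' @param graphs List of \code{mol_graph} objects (or character SMILES,
#'   parsed on the fly).
#' @param spec Descriptor names (see \code{\link{compute_descriptor_block}}).
#' @param ids Row names; defaults to graph source ids.
#' @inheritParams compute_descriptor_block
#' @return Numeric matrix (compounds x descriptors) with a logical
#'   \code{"pad"} matrix attribute.
#' @export
compute_descriptor_matrix <- function(graphs, spec = final_model_descriptors(),
                                      ids = NULL,
                                      properties = atom_property_table(),
                                      dipoles = bond_dipole_table()) {
  graphs <- lapply(graphs, function(g) {
    if (is.character(g)) parse_molecule(g, "smiles", properties = properties) else g
  })
  if (is.null(ids)) ids <- vapply(graphs, function(g) g$source_id, character(1))
  X <- matrix(NA_real_, length(graphs), length(spec),
              dimnames = list(ids, spec))
  P <- matrix(FALSE, length(graphs), length(spec),
              dimnames = list(ids, spec))
  for (r in seq_along(graphs)) {
    v <- compute_descriptor_block(graphs[[r]], spec, properties, dipoles)
    X[r, ] <- v
    P[r, ] <- attr(v, "pad")
  }
  attr(X, "pad") <- P
  X
}
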