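#' Atomic property table
#'
#' Per-element atomic mass, Sanderson electronegativity, polarizability and
#' van der Waals volume for the elements supported by the descriptor
#' calculators (H, C, N, O, F, P, S, Cl, Br, I). Descriptor weights are
#' carbon-scaled: \code{w = property(element) / property(C)}, so carbon always
#' has weight 1. Values are read from a versioned plain-text table shipped
#' with the package; pass \code{file} to substitute your own table with the
#' same columns.
#'
#' @param file Path to a tab-separated table with columns \code{element},
#'   \code{mass}, \code{sanderson_en}, \code{polarizability},
#'   \code{vdw_volume}. Defaults to the packaged table.
#' @return A data frame with one row per element, rownames set to the element
#'   symbol.
#' @export
atom_property_table <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "atom_properties.tsv", package = "pgpsub",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("element", "mass", "sanderson_en", "polarizability", "vdw_volume")
  if (!all(need %in% names(tab))) {
    stop("atom property table must have columns: ", paste(need, collapse = ", "))
  }
  vals <- as.matrix(tab[, setdiff(need, "element")])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all atomic property values must be finite and strictly positive")
  }
  if (!"C" %in% tab$element) stop("atom property table must contain carbon")
  rownames(tab) <- tab$element
  tab
}

# map a user-facing property name to the table column
.property_column <- function(property) {
  switch(property,
    mass              = "mass",
    electronegativity = "sanderson_en",
    polarizability    = "polarizability",
    volume            = "vdw_volume",
    stop("unknown atomic property '", property, "'; use one of ",
         "mass, volume, electronegativity, polarizability")
  )
}

#' Bond dipole moment table
#'
#' Dipole moments (debye) for heavy-atom bond types, used by the
#' dipole-weighted edge-adjacency descriptors. Lookup is symmetric in the
#' element pair; homonuclear bonds have dipole 0 by convention; a missing
#' (pair, order) combination falls back to the pair's single-bond entry,
#' else 0.
#'
#' @param file Path to a tab-separated table with columns \code{element_a},
#'   \code{element_b}, \code{order}, \code{dipole}. Defaults to the packaged
#'   table.
#' @return A data frame of bond dipole entries.
#' @export
bond_dipole_table <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "bond_dipoles.tsv", package = "pgpsub",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("element_a", "element_b", "order", "dipole")
  if (!all(need %in% names(tab))) {
    stop("bond dipole table must have columns: ", paste(need, collapse = ", "))
  }
  tab
}

# dipole moment of one bond; symmetric in (el_a, el_b); homonuclear -> 0
.bond_dipole <- function(el_a, el_b, order, dipoles) {
  if (el_a == el_b) return(0)
  hit <- (dipoles$element_a == el_a & dipoles$element_b == el_b) |
         (dipoles$element_a == el_b & dipoles$element_b == el_a)
  exact <- hit & dipoles$order == order
  if (any(exact)) return(dipoles$dipole[which(exact)[1L]])
  single <- hit & dipoles$order == "single"
  if (any(single)) return(dipoles$dipole[which(single)[1L]])
  0
}

# conventional bond orders used by the Burden matrix
.bond_order_value <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)
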