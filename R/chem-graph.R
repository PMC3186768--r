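#' Hydrogen-suppressed molecular graph
#'
#' The container every descriptor calculator consumes: an ordered atom list
#' (element symbol, formal charge) and a bond list (atom indices, bond order
#' among single/double/triple/aromatic). Hydrogens are suppressed at parse
#' time; stereochemistry and formal charge are carried but ignored by all
#' descriptors, which are constitution-only.
#'
#' @param elements Character vector of element symbols.
#' @param charges Integer vector of formal charges (recycled from 0).
#' @param bonds Data frame with columns \code{i}, \code{j}, \code{order}.
#' @param source_id Free-text identifier carried through for error messages.
#' @param properties Atom property table used to validate element support.
#' @return An object of class \code{mol_graph}.
#' @export
mol_graph <- function(elements, charges = 0L, bonds = NULL, source_id = "",
                      properties = atom_property_table()) {
  n <- length(elements)
  if (n < 1L) stop("molecule '", source_id, "' has no atoms")
  charges <- rep_len(as.integer(charges), n)
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(), j = integer(), order = character())
  }
  bonds <- as.data.frame(bonds)[, c("i", "j", "order")]
  if (nrow(bonds) > 0L) {
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n)) {
      stop("molecule '", source_id, "': bond endpoint out of range")
    }
    if (any(bonds$i == bonds$j)) {
      stop("molecule '", source_id, "': self-bond not allowed")
    }
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) {
      stop("molecule '", source_id, "': duplicate bond")
    }
    bad <- setdiff(unique(bonds$order), names(.bond_order_value))
    if (length(bad)) {
      stop("molecule '", source_id, "': unknown bond order ",
           paste(bad, collapse = ", "))
    }
  }
  unknown <- setdiff(unique(elements), properties$element)
  if (length(unknown)) {
    stop("molecule '", source_id, "': unsupported element(s) ",
         paste(unknown, collapse = ", "),
         " (not in the atom property table)")
  }
  structure(
    list(atoms = data.frame(element = elements, charge = charges,
                            stringsAsFactors = FALSE),
         bonds = bonds, source_id = source_id),
    class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph '", x$source_id, "': ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds>\n", sep = "")
  invisible(x)
}

#' Number of heavy atoms / bonds
#' @param g A \code{mol_graph}.
#' @return Integer count.
#' @export
n_atoms <- function(g) nrow(g$atoms)

#' @rdname n_atoms
#' @export
n_bonds <- function(g) nrow(g$bonds)

# ---------------------------------------------------------------------------
# SMILES parsing
#
# A compact single-pass parser for the SMILES subset used in this package:
# organic-subset atoms (B excluded), bracket atoms with charge / explicit H /
# isotope / stereo marks, branches, ring closures (including %nn), explicit
# bond symbols - = # : / \, aromatic lowercase atoms, and dot-separated
# fragments. Aromaticity is taken from the input (lowercase atoms, ':' bonds)
# with no re-perception; stereo marks are accepted and discarded.
# ---------------------------------------------------------------------------

.bond_symbol_order <- c("-" = "single", "=" = "double", "#" = "triple",
                        ":" = "aromatic", "/" = "single", "\\" = "single")

.parse_smiles_atoms <- function(s, source_id) {
  el <- character(); ar <- logical(); ch <- integer()
  bi <- integer(); bj <- integer(); bo <- character()
  prev <- NA_integer_; stack <- integer(0)
  pending <- NA_character_            # explicit bond symbol awaiting use
  ring <- list()                      # open ring closures: key -> c(atom, order)

  add_atom <- function(element, aromatic, charge) {
    el[length(el) + 1L] <<- element
    ar[length(ar) + 1L] <<- aromatic
    ch[length(ch) + 1L] <<- charge
    idx <- length(el)
    if (!is.na(prev)) {
      ord <- if (!is.na(pending)) .bond_symbol_order[[pending]]
             else if (ar[prev] && aromatic) "aromatic" else "single"
      bi[length(bi) + 1L] <<- prev; bj[length(bj) + 1L] <<- idx
      bo[length(bo) + 1L] <<- ord
    }
    pending <<- NA_character_
    prev <<- idx
  }

  close_ring <- function(key) {
    if (is.na(prev)) stop("SMILES '", source_id, "': ring digit before any atom")
    exp_ord <- if (!is.na(pending)) .bond_symbol_order[[pending]] else NA_character_
    pending <<- NA_character_
    if (is.null(ring[[key]])) {
      ring[[key]] <<- list(atom = prev, order = exp_ord)
    } else {
      open <- ring[[key]]; ring[[key]] <<- NULL
      ord <- if (!is.na(exp_ord)) exp_ord
             else if (!is.na(open$order)) open$order
             else if (ar[open$atom] && ar[prev]) "aromatic" else "single"
      bi[length(bi) + 1L] <<- open$atom; bj[length(bj) + 1L] <<- prev
      bo[length(bo) + 1L] <<- ord
    }
  }

  s <- trimws(s)
  i <- 1L; n <- nchar(s)
  while (i <= n) {
    c1 <- substr(s, i, i)
    c2 <- if (i < n) substr(s, i, i + 1L) else ""
    if (c1 %in% names(.bond_symbol_order)) {
      pending <- c1; i <- i + 1L
    } else if (c1 == "(") {
      if (is.na(prev)) stop("SMILES '", source_id, "': branch before any atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (c1 == ")") {
      if (!length(stack)) stop("SMILES '", source_id, "': unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L
    } else if (c1 == ".") {
      prev <- NA_integer_; pending <- NA_character_; i <- i + 1L
    } else if (grepl("^[0-9]$", c1)) {
      close_ring(c1); i <- i + 1L
    } else if (c1 == "%") {
      key <- substr(s, i + 1L, i + 2L)
      if (!grepl("^[0-9]{2}$", key)) {
        stop("SMILES '", source_id, "': bad %nn ring closure")
      }
      close_ring(key); i <- i + 3L
    } else if (c1 == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0L) stop("SMILES '", source_id, "': unterminated bracket atom")
      body <- substr(s, i + 1L, i + j - 2L)
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Z][a-z]?|[cnosp])(@{1,2})?(H[0-9]*)?([+-][0-9]*|\\++|-+)?(:[0-9]+)?$",
        body))[[1]]
      if (!length(m)) stop("SMILES '", source_id, "': cannot parse atom [", body, "]")
      sym <- m[3]
      aromatic <- sym %in% c("c", "n", "o", "s", "p")
      element <- if (aromatic) toupper(sym) else sym
      chg_tok <- m[6]
      charge <- if (chg_tok == "") 0L
        else if (grepl("^\\++$", chg_tok)) nchar(chg_tok)
        else if (grepl("^-+$", chg_tok)) -nchar(chg_tok)
        else {
          mag <- sub("^[+-]", "", chg_tok)
          sgn <- if (substr(chg_tok, 1, 1) == "+") 1L else -1L
          sgn * if (mag == "") 1L else as.integer(mag)
        }
      add_atom(element, aromatic, as.integer(charge))
      i <- i + j
    } else if (c2 %in% c("Cl", "Br")) {
      add_atom(c2, FALSE, 0L); i <- i + 2L
    } else if (c1 %in% c("C", "N", "O", "P", "S", "F", "I", "B")) {
      add_atom(c1, FALSE, 0L); i <- i + 1L
    } else if (c1 %in% c("c", "n", "o", "s", "p")) {
      add_atom(toupper(c1), TRUE, 0L); i <- i + 1L
    } else {
      stop("SMILES '", source_id, "': unexpected character '", c1,
           "' at position ", i)
    }
  }
  if (length(stack)) stop("SMILES '", source_id, "': unmatched '('")
  if (length(ring)) stop("SMILES '", source_id, "': unclosed ring bond(s)")
  list(elements = el, charges = ch,
       bonds = data.frame(i = bi, j = bj, order = bo, stringsAsFactors = FALSE))
}

# ---------------------------------------------------------------------------
# MOL / SDF V2000 parsing (via ChemmineR; bond type 4 = aromatic is kept
# verbatim, no aromaticity re-perception)
# ---------------------------------------------------------------------------

.parse_molblock <- function(text, source_id) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("SDF/MOL parsing requires the ChemmineR package")
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (!any(grepl("^\\$\\$\\$\\$", lines))) lines <- c(lines, "$$$$")
  f <- tempfile(fileext = ".sdf")
  on.exit(unlink(f))
  writeLines(lines, f)
  sdfs <- ChemmineR::read.SDFset(f)
  if (length(sdfs) < 1L) stop("no MOL record found in '", source_id, "'")
  sdf <- sdfs[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_[0-9]+$", "", rownames(ab))
  charges <- integer(length(elements))
  # M  CHG lines supersede the atom-block charge column
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    fld <- as.integer(strsplit(trimws(sub("^M  CHG *[0-9]+", "", ln)),
                               " +")[[1]])
    if (length(fld) >= 2L) {
      idx <- fld[seq(1, length(fld), by = 2)]
      val <- fld[seq(2, length(fld), by = 2)]
      charges[idx] <- val
    }
  }
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      type = as.integer(bb[, 3]))
  if (any(!bonds$type %in% 1:4)) {
    stop("MOL record '", source_id, "': unsupported bond type ",
         paste(setdiff(bonds$type, 1:4), collapse = ", "))
  }
  bonds$order <- c("single", "double", "triple", "aromatic")[bonds$type]
  list(elements = elements, charges = charges,
       bonds = bonds[, c("i", "j", "order")])
}

# drop hydrogens and keep the connected fragment with most heavy atoms
.suppress_and_pick_fragment <- function(parsed, source_id) {
  keep <- which(parsed$elements != "H")
  if (!length(keep)) stop("molecule '", source_id, "' has no heavy atoms")
  remap <- integer(length(parsed$elements)); remap[keep] <- seq_along(keep)
  b <- parsed$bonds
  b <- b[parsed$elements[b$i] != "H" & parsed$elements[b$j] != "H", , drop = FALSE]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  el <- parsed$elements[keep]; ch <- parsed$charges[keep]

  # connected components by breadth-first search
  n <- length(el)
  adj <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  comp <- integer(n); nc <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      nc <- nc + 1L
      queue <- v; comp[v] <- nc
      while (length(queue)) {
        u <- queue[1]; queue <- queue[-1]
        for (w in adj[[u]]) if (comp[w] == 0L) { comp[w] <- nc; queue <- c(queue, w) }
      }
    }
  }
  best <- which.max(tabulate(comp))
  sel <- which(comp == best)
  remap2 <- integer(n); remap2[sel] <- seq_along(sel)
  b <- b[comp[b$i] == best & comp[b$j] == best, , drop = FALSE]
  b$i <- remap2[b$i]; b$j <- remap2[b$j]
  list(elements = el[sel], charges = ch[sel], bonds = b)
}

#' Parse a molecule into a hydrogen-suppressed graph
#'
#' Accepts SMILES or an SDF/MOL V2000 record. Hydrogens are removed, aromatic
#' bonds are preserved as order \code{"aromatic"} exactly as written in the
#' input (lowercase SMILES atoms, bond type 4 in MOL blocks), and for
#' multi-fragment inputs (salts, mixtures) only the fragment with the most
#' heavy atoms is retained — substrate classification concerns the parent
#' drug. Elements must appear in the atom property table or parsing fails
#' with an unsupported-element error.
#'
#' @param text Structure string (a SMILES, or the full MOL/SDF record text).
#' @param format One of \code{"smiles"}, \code{"sdf"}, \code{"mol"}.
#' @param source_id Identifier used in error messages; defaults to a
#'   truncation of \code{text}.
#' @param properties Atom property table (see \code{\link{atom_property_table}}).
#' @return A \code{\link{mol_graph}}.
#' @examples
#' g <- parse_molecule("CCO")           # ethanol: 3 atoms, 2 single bonds
#' parse_molecule("c1ccccc1")           # benzene: 6 aromatic bonds
#' parse_molecule("[Na+].CC(=O)[O-]")   # acetate fragment kept, Na+ dropped
#' @export
parse_molecule <- function(text, format = c("smiles", "sdf", "mol"),
                           source_id = NULL,
                           properties = atom_property_table()) {
  format <- match.arg(format)
  if (is.null(source_id)) {
    source_id <- if (format == "smiles") substr(trimws(text), 1, 40)
                 else strsplit(text, "\n")[[1]][1]
  }
  parsed <- if (format == "smiles") .parse_smiles_atoms(text, source_id)
            else .parse_molblock(text, source_id)
  frag <- .suppress_and_pick_fragment(parsed, source_id)
  mol_graph(frag$elements, frag$charges, frag$bonds, source_id = source_id,
            properties = properties)
}

#' Topological distance matrix
#'
#' Entry (i, j) is the number of bonds on the shortest path between atoms i
#' and j (breadth-first search); 0 on the diagonal; \code{NA} for atom pairs
#' in different fragments (unreachable).
#'
#' @param g A \code{mol_graph}.
#' @return A symmetric integer matrix.
#' @export
topological_distance_matrix <- function(g) {
  n <- n_atoms(g)
  adj <- vector("list", n)
  for (k in seq_len(n_bonds(g))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  d <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (w in adj[[u]]) {
        if (is.na(dist[w])) { dist[w] <- dist[u] + 1L; queue <- c(queue, w) }
      }
    }
    d[s, ] <- dist
  }
  d
}

#' Carbon-scaled atomic weights
#'
#' For each atom, \code{property(element) / property(C)}; carbon always maps
#' to 1, so descriptor values are dimensionless regardless of the property.
#'
#' @param g A \code{mol_graph}.
#' @param property One of \code{"mass"}, \code{"volume"},
#'   \code{"electronegativity"}, \code{"polarizability"}.
#' @param properties Atom property table.
#' @return Numeric vector, one weight per atom.
#' @export
atom_weights <- function(g, property = c("mass", "volume", "electronegativity",
                                         "polarizability"),
                         properties = atom_property_table()) {
  property <- match.arg(property)
  col <- .property_column(property)
  unknown <- setdiff(unique(g$atoms$element), properties$element)
  if (length(unknown)) {
    stop("unsupported element(s): ", paste(unknown, collapse = ", "))
  }
  properties[g$atoms$element, col] / properties["C", col]
}
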