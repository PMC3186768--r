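#' Labeled compound dataset
#'
#' Bundles compound ids, binary class labels (1 = P-gp substrate,
#' 0 = non-substrate), an optional descriptor matrix with rows aligned to the
#' ids, and a free-text provenance note per compound.
#'
#' @param ids Character vector of unique compound ids.
#' @param labels Numeric/integer vector of labels in \{0, 1\}.
#' @param X Optional numeric descriptor matrix, one row per compound.
#' @param provenance Optional character vector (assay/reference note).
#' @param compounds Optional data frame of raw compound records.
#' @return An object of class \code{labeled_dataset}.
#' @export
labeled_dataset <- function(ids, labels, X = NULL, provenance = NULL,
                            compounds = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate compound id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(labels) != length(ids)) stop("labels must align with ids")
  if (!all(labels %in% c(0, 1))) {
    stop("class labels must be 0 (non-substrate) or 1 (substrate)")
  }
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != length(ids)) stop("descriptor matrix rows must align with ids")
    rownames(X) <- ids
  }
  structure(list(ids = ids, labels = as.integer(labels), X = X,
                 provenance = provenance, compounds = compounds),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d compounds (%d substrates, %d non-substrates)%s\n",
              length(x$ids), sum(x$labels == 1L), sum(x$labels == 0L),
              if (is.null(x$X)) "" else sprintf(", %d descriptors", ncol(x$X))))
  invisible(x)
}

#' Load a labeled compound table
#'
#' Reads a delimited (tab or comma) text table with columns \code{id},
#' \code{name}, a structure column (\code{smiles} or \code{structure}),
#' \code{class} and optionally \code{source}, and reports the class counts.
#'
#' @param file Path to the table.
#' @return A \code{labeled_dataset} (descriptors unset; see
#'   \code{\link{featurize_dataset}}).
#' @export
load_dataset <- function(file) {
  header <- readLines(file, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(file, header = TRUE, sep = sep, quote = "\"",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("compound table '", file, "' is empty")
  if (!"structure" %in% names(tab) && "smiles" %in% names(tab)) {
    tab$structure <- tab$smiles
  }
  need <- c("id", "name", "structure", "class")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("compound table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  ds <- labeled_dataset(tab$id, tab$class,
                        provenance = if ("source" %in% names(tab)) tab$source,
                        compounds = tab)
  message(sprintf("loaded %d compounds: %d substrates (class 1), %d non-substrates (class 0)",
                  length(ds$ids), sum(ds$labels == 1L), sum(ds$labels == 0L)))
  ds
}

#' Attach a descriptor matrix to a dataset
#'
#' Parses each compound's structure and computes the requested descriptor
#' block (default: the six final-model descriptors).
#'
#' @param ds A \code{labeled_dataset} carrying raw compound records.
#' @param spec Descriptor names.
#' @param format Structure format of the table's structure column.
#' @inheritParams compute_descriptor_block
#' @return The dataset with \code{$X} set (pad flags as the matrix's
#'   \code{"pad"} attribute).
#' @export
featurize_dataset <- function(ds, spec = final_model_descriptors(),
                              format = "smiles",
                              properties = atom_property_table(),
                              dipoles = bond_dipole_table()) {
  if (is.null(ds$compounds)) stop("dataset carries no raw compound records")
  graphs <- lapply(seq_along(ds$ids), function(k) {
    parse_molecule(ds$compounds$structure[k], format, source_id = ds$ids[k],
                   properties = properties)
  })
  ds$X <- compute_descriptor_matrix(graphs, spec, ids = ds$ids,
                                    properties = properties, dipoles = dipoles)
  ds
}

#' Molecular similarity from descriptor profiles
#'
#' Pearson correlation between two compounds' descriptor vectors (descriptor
#' profiles are standardized dataset-wide before calling this, so scale
#' differences between descriptors do not dominate).
#'
#' @param a,b Numeric descriptor vectors over the same descriptor names,
#'   length at least 2.
#' @return Correlation in [-1, 1].
#' @export
molecule_similarity <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    stop("descriptor vectors must share names and have length >= 2")
  }
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b))) {
    stop("descriptor vectors must share the same descriptor names in order")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("similarity undefined for a constant descriptor vector")
  }
  stats::cor(a, b)
}

#' Diversity-based external validation set
#'
#' Reproduces the external-set construction: each class's compounds are
#' placed in descriptor space (z-scored per descriptor over the whole
#' dataset), pairwise molecular similarity is the Pearson correlation of the
#' standardized profiles, the class is divided into
#' \code{subsets_per_class} groups by average-linkage agglomerative
#' clustering on distance 1 - similarity, and one compound is drawn uniformly
#' at random (seeded) from each group. The external set is the union over
#' both classes; the remaining compounds form the training pool.
#'
#' @param ds A \code{labeled_dataset} with a descriptor matrix.
#' @param subsets_per_class Number of similarity groups (and picks) per
#'   class; the default 16 gives a 32-compound external set.
#' @param seed Integer seed for the per-group draws.
#' @return A \code{split_spec}: list with \code{external_ids},
#'   \code{pool_ids}, \code{seed} and a free-text \code{method}.
#' @export
build_external_set <- function(ds, subsets_per_class = 16, seed = 1) {
  if (is.null(ds$X)) stop("dataset has no descriptor matrix; featurize first")
  if (ncol(ds$X) < 2L) stop("need at least 2 descriptors for similarity")
  Z <- scale(ds$X)
  if (any(!is.finite(Z))) {
    stop("constant descriptor column; filter low-information columns first")
  }
  external <- character(0)
  for (cls in c(1L, 0L)) {
    rows <- which(ds$labels == cls)
    if (length(rows) < subsets_per_class) {
      stop("class ", cls, " has ", length(rows), " compounds, fewer than ",
           subsets_per_class, " subsets")
    }
    if (length(rows) == subsets_per_class) {
      external <- c(external, ds$ids[rows])
      next
    }
    sim <- stats::cor(t(Z[rows, , drop = FALSE]))
    hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
    grp <- stats::cutree(hc, k = subsets_per_class)
    set.seed(derive_seed(seed, "external-pick", cls))
    for (gidx in seq_len(subsets_per_class)) {
      members <- rows[grp == gidx]
      pick <- if (length(members) == 1L) members else sample(members, 1L)
      external <- c(external, ds$ids[pick])
    }
  }
  structure(list(external_ids = external,
                 pool_ids = setdiff(ds$ids, external),
                 seed = seed,
                 method = paste("average-linkage clustering on 1 - Pearson",
                                "similarity of z-scored descriptors;",
                                subsets_per_class, "subsets per class")),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> external %d / pool %d (seed %s)\n  %s\n",
              length(x$external_ids), length(x$pool_ids), x$seed, x$method))
  invisible(x)
}

#' Stratified train/test split
#'
#' Splits a compound pool so that the test set has
#' \code{round((1 - train_fraction) * n)} members, allocated across classes
#' proportionally (largest-remainder rounding) so both sides see both
#' classes.
#'
#' @param ids Pool compound ids.
#' @param labels Labels aligned with \code{ids}.
#' @param train_fraction Fraction assigned to training (default 0.8, the
#'   ratio that turns a 165-compound pool into a 33-compound test set).
#' @param seed Integer seed for the shuffle.
#' @return List with \code{train_ids} and \code{test_ids}.
#' @export
split_train_test <- function(ids, labels, train_fraction = 0.8, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1, length(ids) > 0)
  ids <- as.character(ids)
  n_test <- round((1 - train_fraction) * length(ids))
  classes <- sort(unique(labels))
  share <- n_test * tabulate(factor(labels, classes)) / length(ids)
  n_per <- floor(share)
  rem <- order(share - n_per, decreasing = TRUE)
  k <- n_test - sum(n_per)
  if (k > 0) n_per[rem[seq_len(k)]] <- n_per[rem[seq_len(k)]] + 1L
  test_ids <- character(0)
  set.seed(seed)
  for (ci in seq_along(classes)) {
    members <- ids[labels == classes[ci]]
    if (n_per[ci] >= length(members) || (length(members) - n_per[ci]) < 1L) {
      stop("class ", classes[ci], " too small for a stratified split")
    }
    test_ids <- c(test_ids, sample(members, n_per[ci]))
  }
  if (length(test_ids) == 0L || length(test_ids) == length(ids)) {
    stop("degenerate split: adjust train_fraction or pool size")
  }
  list(train_ids = setdiff(ids, test_ids), test_ids = test_ids)
}

#' Write / read a split manifest
#'
#' Plain-text manifest recording the external and pool ids together with the
#' seed and method, so a split is reproducible and auditable.
#'
#' @param split A \code{split_spec}.
#' @param file Output path.
#' @return \code{file}, invisibly (writer); a \code{split_spec} (reader).
#' @export
write_split_manifest <- function(split, file) {
  lines <- c(paste0("# pgpsub split manifest"),
             paste0("seed\t", split$seed),
             paste0("method\t", split$method),
             paste0("external\t", paste(split$external_ids, collapse = ",")),
             paste0("pool\t", paste(split$pool_ids, collapse = ",")))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(file) {
  lines <- grep("^#", readLines(file), value = TRUE, invert = TRUE)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  fields <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "\t"),
                                   character(1)),
                            vapply(kv, `[[`, character(1), 1))
  structure(list(external_ids = strsplit(fields[["external"]], ",")[[1]],
                 pool_ids = strsplit(fields[["pool"]], ",")[[1]],
                 seed = as.integer(fields[["seed"]]),
                 method = fields[["method"]]),
            class = "split_spec")
}
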