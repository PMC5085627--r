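# Haplogroup assignment from a tree of defining variants.

#' Load a haplogroup tree
#'
#' Accepts a TSV (\code{node parent defining_variants}, comma-separated
#' labels, empty parent for the root) or an equivalent JSON array of
#' \code{{node, parent, defining_variants}} objects.  The tree must have a
#' single root, resolve all parent references and contain no cycles;
#' defining variants must parse as canonical labels (PhyloTree-style
#' back-mutations with \code{"!"} are rejected).
#'
#' @param path File path (\code{.tsv}/\code{.txt} or \code{.json}).
#' @return Object of class \code{haplo_tree}: tibble with \code{node},
#'   \code{parent}, \code{variants} (list of character vectors).
#' @export
load_tree <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0L) stop("empty tree file")
    vars <- df$defining_variants
    if (is.character(vars)) vars <- strsplit(vars, ",", fixed = TRUE)
    df <- tibble::tibble(node = df$node, parent = df$parent, variants = vars)
  } else {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = character(0))
    if (nrow(raw) == 0L) stop("empty tree file")
    stopifnot(all(c("node", "parent", "defining_variants") %in% names(raw)))
    df <- tibble::tibble(
      node = raw$node, parent = raw$parent,
      variants = lapply(strsplit(raw$defining_variants, ",", fixed = TRUE),
                        function(v) v[nzchar(v)]))
  }
  df$parent[is.na(df$parent)] <- ""
  validate_tree(df)
}

validate_tree <- function(df) {
  roots <- df$node[df$parent == ""]
  if (length(roots) != 1L)
    stop("tree must have exactly one root, found ", length(roots))
  unknown <- setdiff(df$parent[df$parent != ""], df$node)
  if (length(unknown))
    stop("unknown parent node(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(df$node))
    stop("duplicated node names")
  # reachability from the root doubles as the cycle check
  seen <- roots
  repeat {
    nxt <- df$node[df$parent %in% seen & !df$node %in% seen]
    if (!length(nxt)) break
    seen <- c(seen, nxt)
  }
  if (length(seen) != nrow(df))
    stop("cycle or orphan subtree involving: ",
         paste(setdiff(df$node, seen), collapse = ", "))
  for (v in unlist(df$variants)) parse_variant_label(v)  # incl. "!" rejection
  structure(df, class = c("haplo_tree", class(df)))
}

tree_path <- function(tree, node) {
  path <- character(0)
  cur <- node
  while (nzchar(cur)) {
    path <- c(cur, path)
    cur <- tree$parent[match(cur, tree$node)]
  }
  path
}

path_variants <- function(tree, node) {
  unique(unlist(tree$variants[match(tree_path(tree, node), tree$node)]))
}

#' Score a sample against one haplogroup node
#'
#' Expected variants are all defining variants on the root-to-node path;
#' matched are those present in the sample's variant-label set.  The
#' score is matched/expected (0 for the root, whose path is empty);
#' private variants of the sample are not penalized.
#'
#' @param sample_variants Character vector of canonical labels.
#' @param tree A \code{haplo_tree}.
#' @param node Node name.
#' @return List with \code{matched}, \code{expected}, \code{score}.
#' @export
score_node <- function(sample_variants, tree, node) {
  if (!node %in% tree$node) stop("unknown node: ", node)
  exp_v <- path_variants(tree, node)
  matched <- sum(exp_v %in% sample_variants)
  expected <- length(exp_v)
  list(matched = matched, expected = expected,
       score = if (expected == 0L) 0 else matched / expected)
}

#' Assign the best-supported haplogroup
#'
#' Scores every node and returns the best; ties are broken by greater
#' path depth, then lexicographic node name.  The runner-up (second-best
#' node) is reported alongside.
#'
#' @param sample_variants Character vector of canonical labels.
#' @param tree A \code{haplo_tree}.
#' @return One-row tibble: \code{haplogroup}, \code{matched},
#'   \code{expected}, \code{score}, \code{runner_up}, \code{runner_up_score},
#'   \code{tie}.
#' @export
assign_haplogroup <- function(sample_variants, tree) {
  sc <- lapply(tree$node, function(n) score_node(sample_variants, tree, n))
  score <- vapply(sc, `[[`, numeric(1), "score")
  depth <- vapply(tree$node, function(n) length(tree_path(tree, n)), integer(1))
  ord <- order(-score, -depth, tree$node)
  best <- ord[1L]; second <- if (length(ord) > 1L) ord[2L] else NA_integer_
  if (score[best] == 0) best <- match(tree$node[tree$parent == ""], tree$node)
  tie <- !is.na(second) && score[second] == score[best] &&
    depth[second] == depth[best]
  runner_up <- if (is.na(second)) NA_character_ else tree$node[second]
  runner_up_score <- if (is.na(second)) NA_real_ else score[second]
  tibble::tibble(
    haplogroup = tree$node[best],
    matched = sc[[best]]$matched,
    expected = sc[[best]]$expected,
    score = score[best],
    runner_up = runner_up,
    runner_up_score = runner_up_score,
    tie = tie)
}

#' The bundled mini haplogroup tree
#'
#' A 16-node tree covering the macro-haplogroups M (with C, D, D4, G, Z)
#' and N (with A, A4, B4, B4a, B4g, F, R, Y); defining variants are
#' control-region substitutions of the synthetic reference.
#'
#' @return A \code{haplo_tree}.
#' @export
mini_haplo_tree <- function() {
  df <- tibble::tribble(
    ~node, ~parent, ~defining_variants,
    "mt-MRCA", "", "",
    "M", "mt-MRCA", "A16051G,C16071T",
    "N", "mt-MRCA", "T16093C,C16104T",
    "C", "M", "A16111T,G16129A",
    "D", "M", "C16145T,A16154G",
    "D4", "D", "T249C",
    "G", "M", "C16172T,A16209G",
    "Z", "M", "C16223T,A16234G",
    "A", "N", "C16243T,A16249G",
    "A4", "A", "C16278T,A16290G",
    "B4", "N", "C16304T,A16311G",
    "B4a", "B4", "C16320T,A73G",
    "B4g", "B4", "T93C,C103T",
    "F", "N", "C143T,A152G",
    "R", "N", "T195C,A204G",
    "Y", "N", "C235T,A247G"
  )
  validate_tree(tibble::tibble(
    node = df$node, parent = df$parent,
    variants = lapply(strsplit(df$defining_variants, ",", fixed = TRUE),
                      function(v) v[nzchar(v)])))
}

haplo_leaves <- function(tree) {
  setdiff(tree$node, tree$parent)
}
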