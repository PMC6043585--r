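#' Sample an initial Erdős–Rényi social network
#'
#' Networks are plain symmetric 0/1 integer matrices with a zero diagonal;
#' individual `i` is row/column `i`. Each unordered pair is linked
#' independently with probability `p0`. Simulations only use this as a
#' starting point: a selection-free burn-in of the social-inheritance
#' process erases the initial density.
#'
#' @param n Population size (at least 3).
#' @param p0 Link probability for each pair, in \[0, 1\].
#' @return An `n` x `n` symmetric 0/1 integer matrix.
#' @examples
#' net <- initial_network(20, 0.1)
#' mean(rowSums(net))
#' @export
initial_network <- function(n, p0) {
  if (!is.numeric(n) || length(n) != 1L || n < 3 || n != round(n)) {
    stop("`n` must be a single integer >= 3", call. = FALSE)
  }
  check_probability(p0, "p0")
  n <- as.integer(n)
  net <- matrix(0L, n, n)
  upper <- upper.tri(net)
  net[upper] <- as.integer(runif(sum(upper)) < p0)
  net[lower.tri(net)] <- t(net)[lower.tri(net)]
  net
}

#' Social ties of a newborn individual
#'
#' Implements the three-part linking rule of social inheritance: the newborn
#' connects to its parent with certainty, to each current neighbour of the
#' parent independently with probability `p_n`, and to each living
#' individual that is neither the parent nor one of its neighbours
#' independently with probability `p_r`. Call this after the dead individual
#' has been removed, so "neighbour of the parent" is evaluated at the time
#' of birth.
#'
#' @param net Symmetric 0/1 adjacency matrix of the living individuals.
#' @param parent Index of the reproducing individual.
#' @param p_n Probability of inheriting each parental tie, in \[0, 1\].
#' @param p_r Probability of linking to each non-neighbour of the parent.
#' @param exclude Indices that are not candidates (used by
#'   [replace_individual()] to keep the newborn from linking to its own
#'   freed slot).
#' @return Sorted integer vector of individuals the newborn links to;
#'   always contains `parent`.
#' @export
newborn_links <- function(net, parent, p_n, p_r, exclude = integer()) {
  check_network(net)
  n <- nrow(net)
  if (!is.numeric(parent) || length(parent) != 1L || parent < 1 ||
      parent > n || parent != round(parent)) {
    stop("`parent` is not a living individual of `net`", call. = FALSE)
  }
  check_probability(p_n, "p_n")
  check_probability(p_r, "p_r")
  parent <- as.integer(parent)
  others <- setdiff(seq_len(n), c(parent, exclude))
  is_nb <- net[parent, others] == 1L
  prob <- ifelse(is_nb, p_n, p_r)
  linked <- others[runif(length(others)) < prob]
  sort(c(parent, linked))
}

#' Replace a dead individual by a newborn
#'
#' The death-birth structural update: the dead individual and all its
#' incident edges are removed first, then the newborn occupies the freed
#' slot and is wired by [newborn_links()] applied to the post-removal
#' network (a tie to the dead individual can therefore never be inherited).
#' Population size is conserved and the newborn has degree at least 1 (its
#' parent).
#'
#' @inheritParams newborn_links
#' @param dead Index of the dying individual; must differ from `parent`.
#' @return The updated adjacency matrix, with the newborn at index `dead`.
#' @export
replace_individual <- function(net, dead, parent, p_n, p_r) {
  check_network(net)
  n <- nrow(net)
  if (!is.numeric(dead) || length(dead) != 1L || dead < 1 || dead > n ||
      dead != round(dead)) {
    stop("`dead` is not a living individual of `net`", call. = FALSE)
  }
  if (dead == parent) {
    stop("`dead` and `parent` must be different individuals", call. = FALSE)
  }
  dead <- as.integer(dead)
  net[dead, ] <- 0L
  net[, dead] <- 0L
  links <- newborn_links(net, parent, p_n, p_r, exclude = dead)
  net[dead, links] <- 1L
  net[links, dead] <- 1L
  net
}

#' Edge list of a network as a tibble
#'
#' @param net Symmetric 0/1 adjacency matrix.
#' @param zero_based Use 0-based ids (the on-disk convention)?
#' @return A tibble with columns `from` and `to`, one row per undirected
#'   edge, `from < to`.
#' @export
network_edges <- function(net, zero_based = FALSE) {
  check_network(net)
  idx <- which(upper.tri(net) & net == 1L, arr.ind = TRUE)
  off <- if (zero_based) 1L else 0L
  tibble::tibble(from = idx[, 1L] - off, to = idx[, 2L] - off)
}

#' Export a network snapshot as plain text
#'
#' Writes a two-column whitespace-separated edge list (`i j` per line,
#' `i < j`, 0-based ids) and, when individual attributes are supplied, a
#' companion CSV with one row per individual (id, type, p_n, p_r, degree)
#' for use with standard graph tools.
#'
#' @param net Symmetric 0/1 adjacency matrix.
#' @param path Output path for the edge list.
#' @param types,p_n,p_r Optional per-individual attribute vectors; when all
#'   are given, attributes are written to `attr_path`.
#' @param attr_path Path of the attribute CSV; defaults to `path` with an
#'   `_attrs.csv` suffix.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(net, path, types = NULL, p_n = NULL, p_r = NULL,
                           attr_path = NULL) {
  edges <- network_edges(net, zero_based = TRUE)
  writeLines(sprintf("%d %d", edges$from, edges$to), path)
  if (!is.null(types)) {
    if (is.null(attr_path)) {
      attr_path <- paste0(sub("\\.[^.]*$", "", path), "_attrs.csv")
    }
    attrs <- data.frame(
      id = seq_len(nrow(net)) - 1L,
      type = as.integer(types),
      p_n = if (is.null(p_n)) NA_real_ else p_n,
      p_r = if (is.null(p_r)) NA_real_ else p_r,
      degree = rowSums(net)
    )
    write.csv(attrs, attr_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

check_network <- function(net) {
  if (!is.matrix(net) || nrow(net) != ncol(net)) {
    stop("`net` must be a square adjacency matrix", call. = FALSE)
  }
  invisible(net)
}

check_probability <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(p)
}
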