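#' Parse a GO ontology in OBO format
#'
#' Minimal reader for OBO 1.2/1.4 `[Term]` stanzas: keeps `id`, `name`,
#' `namespace` and `is_a` relations; obsolete terms are skipped, as are
#' `is_a` references to terms absent from the file (counted). Only the plain
#' `is_a` hierarchy is used; `part_of` and other relationships are ignored.
#'
#' Depths are precomputed per namespace as the shortest `is_a` hop distance
#' from the namespace root (a term without parents); `depth(root) = 0`.
#'
#' @param path path to an OBO file.
#' @return An object of class `go_dag`: list with `terms` (character),
#'   `parents` (named list of parent-term vectors), `roots`, `depth` (named
#'   integer), `namespace` (named character) and `dropped_parents` (count of
#'   is_a references to unknown terms).
#' @export
read_obo <- function(path) {
  assert_file(path, "OBO")
  lines <- readLines(path)
  stanza_starts <- grep("^\\[", lines)
  term_ids <- character()
  parents <- list()
  namespaces <- character()
  current <- NULL
  cur_parents <- character()
  cur_ns <- NA_character_
  cur_obsolete <- FALSE
  flush <- function() {
    if (!is.null(current) && !cur_obsolete) {
      term_ids[[length(term_ids) + 1L]] <<- current
      parents[[current]] <<- unique(cur_parents)
      namespaces[[current]] <<- cur_ns
    }
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (grepl("^\\[", ln)) {
      flush()
      current <- NULL
      cur_parents <- character()
      cur_ns <- NA_character_
      cur_obsolete <- FALSE
      in_term <- identical(ln, "[Term]")
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id: ")) {
      current <- sub("^id: ", "", ln)
    } else if (startsWith(ln, "namespace: ")) {
      cur_ns <- sub("^namespace: ", "", ln)
    } else if (startsWith(ln, "is_a: ")) {
      v <- sub("^is_a: ", "", ln)
      v <- sub("\\s*!.*$", "", v)        # strip trailing comment
      v <- sub("\\s*\\{.*\\}\\s*$", "", v)  # strip trailer qualifiers
      cur_parents <- c(cur_parents, trimws(v))
    } else if (grepl("^is_obsolete: *true", ln)) {
      cur_obsolete <- TRUE
    }
  }
  flush()
  if (length(term_ids) == 0L) stop_input("no [Term] stanzas found in ", path)
  go_dag(term_ids, parents[term_ids], namespaces[term_ids])
}

#' Construct a GO DAG from term/parent lists
#'
#' @param terms character vector of term identifiers.
#' @param parents named list (per term) of parent-term identifiers; `is_a`
#'   references to unknown terms are dropped and counted.
#' @param namespace optional named character vector of namespaces; terms
#'   without one inherit `"default"`.
#' @return A `go_dag`; a cyclic `is_a` structure raises a validation error.
#' @export
go_dag <- function(terms, parents = list(), namespace = NULL) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop_input("duplicate term identifiers")
  pl <- rep(list(character()), length(terms))
  names(pl) <- terms
  dropped <- 0L
  for (t in intersect(names(parents), terms)) {
    p <- as.character(parents[[t]])
    known <- p %in% terms
    dropped <- dropped + sum(!known)
    pl[[t]] <- unique(p[known])
  }
  ns <- rep("default", length(terms))
  names(ns) <- terms
  if (!is.null(namespace)) {
    namespace <- namespace[!is.na(namespace)]
    common <- intersect(names(namespace), terms)
    ns[common] <- as.character(namespace[common])
  }
  # topological order (Kahn): leftovers indicate an is_a cycle
  n_par <- lengths(pl)
  children <- rep(list(character()), length(terms))
  names(children) <- terms
  for (t in terms) {
    for (p in pl[[t]]) children[[p]] <- c(children[[p]], t)
  }
  roots <- terms[n_par == 0L]
  depth <- rep(NA_integer_, length(terms))
  names(depth) <- terms
  depth[roots] <- 0L
  queue <- roots
  remaining <- n_par
  processed <- 0L
  while (length(queue) > 0L) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    processed <- processed + 1L
    for (ch in children[[t]]) {
      cand <- depth[[t]] + 1L
      if (is.na(depth[[ch]]) || cand < depth[[ch]]) depth[[ch]] <- cand
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (processed < length(terms)) {
    stop_input("cyclic is_a structure detected among GO terms")
  }
  structure(list(
    terms = terms, parents = pl, roots = roots, depth = depth,
    namespace = ns, dropped_parents = dropped
  ), class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("GO DAG: %d terms, %d root(s), %d namespace(s), max depth %d\n",
              length(x$terms), length(x$roots), length(unique(x$namespace)),
              max(x$depth)))
  invisible(x)
}

# transitive is_a ancestors including the term itself
go_ancestors <- function(term, dag) {
  seen <- character()
  stack <- term
  while (length(stack) > 0L) {
    t <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (t %in% seen) next
    seen <- c(seen, t)
    stack <- c(stack, dag$parents[[t]])
  }
  seen
}

#' Standardized GO terms
#'
#' Maps a term to its set of standardized terms: the term itself and its
#' transitive `is_a` ancestors whose depth from the namespace root is between
#' 1 and 5 inclusive. The root (depth 0) is excluded, as are the term and
#' ancestors deeper than 5.
#'
#' @param term a term identifier present in `dag`.
#' @param dag a [go_dag()].
#' @return Character vector of standardized term identifiers (possibly
#'   empty), sorted.
#' @export
standardized_terms <- function(term, dag) {
  stopifnot(inherits(dag, "go_dag"))
  if (!(term %in% dag$terms)) stop_input("unknown GO term: ", term)
  anc <- go_ancestors(term, dag)
  d <- dag$depth[anc]
  sort(anc[d >= 1L & d <= 5L], method = "radix")
}

#' Construct protein GO annotations
#'
#' @param protein,term equal-length character vectors of protein-to-term
#'   assignments; terms absent from `dag` are dropped and counted.
#' @param dag a [go_dag()].
#' @return An object of class `go_annotations`: list with `terms_of` (named
#'   list of term sets per protein) and `dropped_terms` (count).
#' @export
go_annotations <- function(protein, term, dag) {
  stopifnot(inherits(dag, "go_dag"))
  protein <- as.character(protein)
  term <- as.character(term)
  known <- term %in% dag$terms
  dropped <- sum(!known)
  if (dropped > 0L) {
    warning(sprintf("%d annotation(s) reference unknown GO terms; dropped", dropped))
  }
  terms_of <- lapply(split(term[known], protein[known]),
                     function(v) sort(unique(v), method = "radix"))
  structure(list(terms_of = terms_of, dropped_terms = dropped),
            class = "go_annotations")
}

#' @export
print.go_annotations <- function(x, ...) {
  cat(sprintf("GO annotations: %d annotated protein(s), %d term assignment(s)\n",
              length(x$terms_of), sum(lengths(x$terms_of))))
  invisible(x)
}

#' Read protein GO annotations
#'
#' Two formats: GAF 2.x (tab-separated, `!` comment lines; column 2 is the
#' protein key, column 5 the GO identifier; rows whose qualifier contains
#' `NOT` are skipped) and a plain two-column protein/term table (with
#' `#` comments).
#'
#' @param path path to the annotation file.
#' @param dag a [go_dag()] used to validate terms.
#' @param fmt `"gaf"` or `"twocol"`.
#' @return A [go_annotations()].
#' @export
read_annotations <- function(path, dag, fmt = c("gaf", "twocol")) {
  fmt <- match.arg(fmt)
  assert_file(path, "annotation")
  lines <- readLines(path)
  if (fmt == "gaf") {
    lines <- lines[!startsWith(lines, "!") & nzchar(trimws(lines))]
    if (length(lines) == 0L) return(go_annotations(character(), character(), dag))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 5L)
    if (length(bad) > 0L) {
      stop_input("malformed GAF line (fewer than 5 columns): ", lines[bad[1L]])
    }
    prot <- vapply(parts, `[[`, character(1), 2L)
    qual <- vapply(parts, `[[`, character(1), 4L)
    term <- vapply(parts, `[[`, character(1), 5L)
    keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
    go_annotations(prot[keep], term[keep], dag)
  } else {
    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    lines <- lines[keep]
    if (length(lines) == 0L) return(go_annotations(character(), character(), dag))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad) > 0L) {
      stop_input("malformed two-column annotation line: ", lines[bad[1L]])
    }
    m <- do.call(rbind, parts)
    go_annotations(m[, 1L], m[, 2L], dag)
  }
}

#' Read ontology and annotations together
#'
#' @param obo_path path to an OBO ontology file.
#' @param annot_path path to the annotation file.
#' @param annot_fmt `"gaf"` or `"twocol"`.
#' @return A list with elements `dag` ([go_dag()]) and `annotations`
#'   ([go_annotations()]).
#' @export
read_go <- function(obo_path, annot_path, annot_fmt = c("gaf", "twocol")) {
  dag <- read_obo(obo_path)
  ann <- read_annotations(annot_path, dag, fmt = annot_fmt)
  list(dag = dag, annotations = ann)
}
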