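#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' Parsing is delegated to ChemmineR/OpenBabel; the result keeps only what
#' graph-complexity scoring needs: heavy-atom element symbols and the bond
#' list with integer orders (hydrogens implicit).
#'
#' @param smiles a single SMILES string.
#' @return list with `elements` (character) and `bonds` (data.frame
#'   `from`, `to`, `order`).
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  .check_smiles_syntax(smiles)
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("ChemmineR is required for SMILES parsing")
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(c(mol = smiles))),
    error = function(e) NULL)
  ok <- !is.null(sdf) && length(sdf) == 1L &&
    nrow(ChemmineR::atomblock(sdf[[1]])) >= 1L
  if (!ok)
    stop("could not parse SMILES '", smiles, "'")
  ab <- ChemmineR::atomblock(sdf[[1]])
  elements <- sub("_.*$", "", rownames(ab))
  bb <- tryCatch(ChemmineR::bondblock(sdf[[1]]), error = function(e) NULL)
  bonds <- if (is.null(bb) || NROW(bb) == 0L || NCOL(bb) < 3L)
    data.frame(from = integer(), to = integer(), order = integer())
  else data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                  order = as.integer(bb[, 3]))
  # OpenBabel may emit order 4 for aromatic bonds it could not kekulize;
  # treat those as order 1 rings plus one (arbitrary but deterministic)
  bonds$order[bonds$order > 3L] <- 1L
  list(elements = elements, bonds = bonds)
}

# Cheap structural validation so malformed strings are rejected with the
# position of the first offending character (the downstream parser is
# lenient about some malformed input).
.check_smiles_syntax <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  depth <- 0L; brk <- 0L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      if (i == 1L || chars[i - 1L] %in% c("(", "."))
        stop("could not parse SMILES '", smiles,
             "': misplaced '(' at position ", i)
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("could not parse SMILES '", smiles,
             "': unmatched ')' at position ", i)
    } else if (ch == "[") brk <- brk + 1L
    else if (ch == "]") {
      brk <- brk - 1L
      if (brk < 0L)
        stop("could not parse SMILES '", smiles,
             "': unmatched ']' at position ", i)
    }
  }
  if (depth != 0L)
    stop("could not parse SMILES '", smiles, "': unclosed '('")
  if (brk != 0L)
    stop("could not parse SMILES '", smiles, "': unclosed '['")
  ring <- gsub("%[0-9]{2}", "R", gsub("\\[[^]]*\\]", "A", smiles))
  digs <- c(regmatches(ring, gregexpr("[0-9]", ring))[[1]],
            regmatches(ring, gregexpr("R", ring))[[1]])
  if (length(digs) && any(table(digs) %% 2 != 0))
    stop("could not parse SMILES '", smiles, "': unpaired ring closure")
  invisible(TRUE)
}

# Morgan-style refinement of atom equivalence classes: start from element
# symbols, iteratively absorb the multiset of (bond order, neighbour class)
# labels until the partition stabilizes. Approximates automorphism orbits.
.atom_classes <- function(g) {
  n <- length(g$elements)
  lab <- g$elements
  cls <- match(lab, unique(lab))
  if (!nrow(g$bonds)) return(cls)
  for (it in seq_len(n)) {
    nb <- vector("list", n)
    for (i in seq_len(nrow(g$bonds))) {
      a <- g$bonds$from[i]; b <- g$bonds$to[i]; o <- g$bonds$order[i]
      nb[[a]] <- c(nb[[a]], paste0(o, ":", cls[b]))
      nb[[b]] <- c(nb[[b]], paste0(o, ":", cls[a]))
    }
    lab2 <- vapply(seq_len(n), function(i)
      paste(cls[i], paste(sort(nb[[i]]), collapse = ","), sep = "|"), "")
    cls2 <- match(lab2, unique(lab2))
    if (length(unique(cls2)) == length(unique(cls))) { cls <- cls2; break }
    cls <- cls2
  }
  cls
}

#' Bertz molecular-complexity index
#'
#' The two-term graph-complexity score `C = C(eta) + C(E)`: the
#' connectivity term is the information content of the distribution of
#' bond-pair (two-edge path) equivalence classes, `C(eta) = 2 eta log2 eta
#' - sum_i eta_i log2 eta_i`, where `eta` counts pairs of adjacent edges
#' (a bond of order `b` contributing `b` parallel edges) and classes are
#' induced by Morgan-refined atom equivalence classes; the element term
#' applies the same information formula to the partition of heavy atoms by
#' element. Hydrogens are implicit; formal charges are not scored. A graph
#' with no adjacent bond pairs has connectivity term 0.
#'
#' @param x a SMILES string or a graph as returned by [parse_smiles()].
#' @return list with `total`, `connectivity`, `element`, `n_connections`.
#' @export
bertz_index <- function(x) {
  g <- if (is.character(x)) parse_smiles(x) else x
  stopifnot(is.list(g), !is.null(g$elements), !is.null(g$bonds))
  cls <- .atom_classes(g)
  info <- function(sizes) {
    nn <- sum(sizes)
    if (nn == 0) return(0)
    2 * nn * log2(nn) - sum(sizes * log2(sizes))
  }
  # expand multiple bonds into parallel edges, then enumerate adjacent
  # edge pairs at every atom, labelling each pair by the (refined) classes
  # of the three atoms involved and the two bond orders
  conn_labels <- character()
  if (nrow(g$bonds)) {
    b <- g$bonds[rep(seq_len(nrow(g$bonds)), g$bonds$order), c("from", "to", "order")]
    for (a in seq_along(g$elements)) {
      inc <- which(b$from == a | b$to == a)
      if (length(inc) < 2L) next
      prs <- utils::combn(inc, 2L)
      for (j in seq_len(ncol(prs))) {
        e1 <- prs[1, j]; e2 <- prs[2, j]
        oth <- function(e) if (b$from[e] == a) b$to[e] else b$from[e]
        arm <- sort(c(paste0(b$order[e1], ":", cls[oth(e1)]),
                      paste0(b$order[e2], ":", cls[oth(e2)])))
        conn_labels <- c(conn_labels,
                         paste(cls[a], arm[1], arm[2], sep = "|"))
      }
    }
  }
  c_eta <- info(as.numeric(table(conn_labels)))
  c_e <- info(as.numeric(table(g$elements)))
  list(total = c_eta + c_e, connectivity = c_eta, element = c_e,
       n_connections = length(conn_labels))
}

#' Bundled blocker structures (reconstructions)
#'
#' Reads the bundled table of blocker structures: the PEG-based bis-QA
#' blockers (octa(ethylene glycol) backbone, two terminal quaternary
#' ammonium groups) and the classical comparator blockers. All structures
#' are reconstructions from published structural descriptions, not
#' deposited structures; affinities for the comparators are approximate
#' literature values. See the file header of
#' `inst/extdata/blocker_structures_synthetic.tsv`.
#'
#' @return data.frame with `name`, `pq_class`, `kd_uM`, `smiles`.
#' @export
blocker_structures <- function() {
  path <- system.file("extdata", "blocker_structures_synthetic.tsv",
                      package = "scblock", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a name-tab-SMILES file
#'
#' One molecule per line, `name<TAB>smiles`; lines starting with `#` are
#' comments.
#'
#' @param path input file.
#' @return data.frame with `name` and `smiles`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("expected name<TAB>smiles at line ", bad[1])
  data.frame(name = vapply(parts, `[[`, "", 1L),
             smiles = vapply(parts, `[[`, "", 2L))
}

#' Affinity-versus-complexity comparison table
#'
#' Scores every record with [bertz_index()], returns a scatter-ready table
#' of complexity against `log10(Kd)` by compound class, and the
#' fold-complexity ratio of a named reference compound to the mean of a
#' comparison set.
#'
#' @param records data.frame with `name`, `smiles`, `kd_uM` and optionally
#'   `pq_class`; defaults to [blocker_structures()].
#' @param reference name of the reference compound for the fold ratio.
#' @param comparison_set names whose mean complexity forms the denominator.
#' @return list with `table` (name, pq_class, bertz, log10_kd) and
#'   `fold_ratio`.
#' @export
affinity_complexity_table <- function(records = blocker_structures(),
                                      reference = "tubocurarine",
                                      comparison_set = c("PQ2", "PQ3", "PQ4", "PQ5")) {
  stopifnot(all(c("name", "smiles", "kd_uM") %in% names(records)))
  if (any(records$kd_uM <= 0)) stop("kd_uM must be positive for all records")
  bertz <- vapply(records$smiles, function(s) bertz_index(s)$total, 0)
  tab <- data.frame(name = records$name,
                    pq_class = if (!is.null(records$pq_class))
                      records$pq_class else NA_character_,
                    bertz = unname(bertz),
                    log10_kd = log10(records$kd_uM))
  ratio <- NA_real_
  if (reference %in% tab$name && all(comparison_set %in% tab$name))
    ratio <- tab$bertz[tab$name == reference] /
      mean(tab$bertz[tab$name %in% comparison_set])
  list(table = tab, fold_ratio = ratio)
}
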