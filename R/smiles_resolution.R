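# Name-to-SMILES resolution through a pluggable backend and structure
# filters that count carbons and aromatic rings directly on SMILES strings.

.smiles_backend_registry <- new.env(parent = emptyenv())

#' Register a name-to-SMILES backend
#'
#' A backend is a function `function(name) -> SMILES string or NULL`. The
#' built-in `"lookup"` backend resolves names through a TSV lookup table and
#' is the test default; adapters for external systematic-name parsers can be
#' registered under other ids.
#'
#' @param name Backend id.
#' @param fn Backend function.
#' @export
register_smiles_backend <- function(name, fn) {
  assign(name, fn, envir = .smiles_backend_registry)
  invisible(name)
}

#' Construct the lookup-table SMILES backend
#'
#' @param path TSV file of `name<TAB>smiles` (default: packaged table).
#' @return Backend function for [register_smiles_backend()].
#' @export
lookup_smiles_backend <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "name_smiles.tsv", package = "tadfminer")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  # comment lines only at full-line starts; '#' is meaningful inside SMILES
  lines <- lines[!stringr::str_starts(lines, "#")]
  parts <- stringr::str_split_fixed(lines, "\t", 2)
  header <- tolower(parts[1, ])
  stopifnot(identical(header, c("name", "smiles")))
  parts <- parts[-1, , drop = FALSE]
  lut <- setNames(parts[, 2], tolower(normalize_name(parts[, 1])))
  function(name) {
    hit <- unname(lut[tolower(normalize_name(name))])
    if (length(hit) != 1 || is.na(hit)) NULL else hit
  }
}

#' Resolve a chemical name to a SMILES string
#'
#' @param name Compound name (normalized internally).
#' @param backend Backend function or registered backend id.
#' @return List `(text, source)` of class `tadf_smiles`, or `NULL` when the
#'   name cannot be resolved (partial or trivial names keep their record but
#'   are excluded from the SMILES subsidiary output).
#' @export
name_to_smiles <- function(name, backend = "lookup") {
  if (is.character(backend)) {
    if (exists(backend, envir = .smiles_backend_registry)) {
      fn <- get(backend, envir = .smiles_backend_registry)
    } else if (backend == "lookup") {
      fn <- lookup_smiles_backend()
      register_smiles_backend("lookup", fn)
    } else stop("unregistered SMILES backend: ", backend)
  } else fn <- backend
  s <- fn(name)
  if (is.null(s)) return(NULL)
  structure(list(text = s, source = "backend"), class = "tadf_smiles")
}

# Tokenize a SMILES string into atoms with aromaticity flags and ring-closure
# events. Two-letter organic-subset elements (Cl, Br) are handled; bracket
# atoms are parsed for their element symbol.
tokenize_smiles <- function(smiles) {
  s <- if (inherits(smiles, "tadf_smiles")) smiles$text else smiles
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  atoms <- list()        # list of (element, aromatic)
  closures <- list()     # ring-closure digit -> open atom index (while open)
  pairs <- list()        # completed (atom_i, atom_j)
  open <- list()
  i <- 1L
  last_atom <- 0L
  add_atom <- function(element, aromatic) {
    atoms[[length(atoms) + 1L]] <<- list(element = element, aromatic = aromatic)
    last_atom <<- length(atoms)
  }
  handle_closure <- function(key) {
    if (last_atom == 0L) stop("ring closure before any atom in SMILES: ", s)
    if (!is.null(open[[key]])) {
      pairs[[length(pairs) + 1L]] <<- c(open[[key]], last_atom)
      open[[key]] <<- NULL
    } else {
      open[[key]] <<- last_atom
    }
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unbalanced bracket atom in SMILES: ", s)
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- stringr::str_match(inner, "^[0-9]*([A-Za-z][a-z]?)")
      el <- m[1, 2]
      if (is.na(el)) stop("cannot read bracket atom '", inner, "' in: ", s)
      aromatic <- stringr::str_detect(stringr::str_sub(el, 1, 1), "[a-z]")
      add_atom(stringr::str_to_title(el), aromatic)
      i <- j + 1L
    } else if (ch %in% c("C", "B", "N", "O", "P", "S", "F", "I")) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE); i <- i + 2L
      } else {
        add_atom(ch, FALSE); i <- i + 1L
      }
    } else if (ch %in% c("c", "b", "n", "o", "p", "s")) {
      add_atom(stringr::str_to_upper(ch), TRUE); i <- i + 1L
    } else if (stringr::str_detect(ch, "[0-9]")) {
      handle_closure(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %nn ring closure in SMILES: ", s)
      handle_closure(paste0(chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\", "(", ")", ".", "+", "@", "H")) {
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in SMILES: ", s)
    }
  }
  if (length(open) && any(!vapply(open, is.null, logical(1)))) {
    stop("unpaired ring-closure digit in SMILES: ", s)
  }
  depth <- sum(chars == "(") - sum(chars == ")")
  if (depth != 0) stop("unbalanced parentheses in SMILES: ", s)
  list(atoms = atoms, pairs = pairs)
}

#' Count carbon atoms in a SMILES string
#'
#' Counts `C`/`c` atoms outside brackets (two-letter elements such as Cl are
#' not miscounted) plus bracket atoms whose element is carbon.
#'
#' @param smiles SMILES string or `tadf_smiles`.
#' @return Integer carbon count.
#' @export
count_carbons <- function(smiles) {
  tok <- tokenize_smiles(smiles)
  sum(vapply(tok$atoms, function(a) a$element == "C", logical(1)))
}

#' Count aromatic rings in a SMILES string
#'
#' Counts ring-closure digit pairs whose both endpoint atoms are aromatic;
#' fused systems count one ring per closure pair. This closure-pair rule is
#' exact for SMILES written with one closure per ring.
#'
#' @param smiles SMILES string or `tadf_smiles`.
#' @return Integer aromatic ring count.
#' @export
count_aromatic_rings <- function(smiles) {
  tok <- tokenize_smiles(smiles)
  sum(vapply(tok$pairs, function(p) {
    tok$atoms[[p[1]]]$aromatic && tok$atoms[[p[2]]]$aromatic
  }, logical(1)))
}

#' Structure filter on carbon and aromatic-ring counts
#'
#' Molecules with fewer than 24 carbons and fewer than five aromatic rings
#' are removed (both conditions must hold, matching the conjunctive removal
#' rule; `mode = "or"` switches to the disjunctive reading).
#'
#' @param smiles SMILES string or `tadf_smiles`.
#' @param min_carbons,min_aromatic_rings Thresholds (defaults 24 and 5).
#' @param mode `"and"` (default) or `"or"` combination of the two removal
#'   conditions.
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
passes_structure_filter <- function(smiles, min_carbons = 24,
                                    min_aromatic_rings = 5,
                                    mode = c("and", "or")) {
  mode <- match.arg(mode)
  few_c <- count_carbons(smiles) < min_carbons
  few_r <- count_aromatic_rings(smiles) < min_aromatic_rings
  drop <- if (mode == "and") few_c && few_r else few_c || few_r
  !drop
}

#' Attach SMILES strings to records and apply the structure filter
#'
#' Builds the subsidiary record set: every record whose compound name
#' resolves to a SMILES string that passes the structure filter gains a
#' `compound$smiles` field; all other records are excluded from the output.
#'
#' @param records List of `tadf_candidate`/clean records.
#' @param backend SMILES backend id or function.
#' @param filter Apply [passes_structure_filter()] (default `TRUE`).
#' @return List of records with `compound$smiles` set.
#' @export
attach_smiles <- function(records, backend = "lookup", filter = TRUE) {
  out <- list()
  for (r in records) {
    if (is.null(r$compound) || !length(r$compound$names)) next
    s <- NULL
    for (nm in r$compound$names) {
      s <- name_to_smiles(nm, backend)
      if (!is.null(s)) break
    }
    if (is.null(s)) next
    if (filter && !passes_structure_filter(s)) next
    r$compound$smiles <- s$text
    out[[length(out) + 1L]] <- r
  }
  out
}
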