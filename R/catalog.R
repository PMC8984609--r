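# Module catalog: definition, plain-text grammar, validation.
#
# A module is an ordered list of steps. Each step is a set of alternatives
# (comma-separated in the text format); each alternative is a set of
# identifiers that must ALL be present (a complex, '+'-joined). Key-enzyme
# clauses use the same grammar: a module can only be assigned when every
# key clause has at least one alternative fully present, regardless of
# overall completeness.
#
# The grammar is deliberately a subset of KEGG DEFINITION syntax: the '-'
# (optional component) and nested-parenthesis constructs are omitted because
# none of the shipped gene sets need them.
#
# Text format, one module per block:
#
#   MODULE <module_id> <category> <name ...>
#   STEP   <alt>[,<alt>...]          # alt = id or id+id+...
#   KEY    <alt>[,<alt>...]
#
# '#' starts a comment; blank lines are ignored.

MODULE_CATEGORIES <- c("carbon_fixation", "nitrogen", "sulfur", "phosphorus",
                       "cobalamin", "auxin", "ethylene")

parse_alternatives <- function(expr, where = "") {
  alts <- strsplit(expr, ",", fixed = TRUE)[[1]]
  if (length(alts) == 0L || any(!nzchar(alts)))
    stop(sprintf("empty alternative%s", where), call. = FALSE)
  lapply(alts, function(a) {
    ids <- strsplit(a, "+", fixed = TRUE)[[1]]
    if (length(ids) == 0L || any(!nzchar(ids)))
      stop(sprintf("empty identifier in complex '%s'%s", a, where), call. = FALSE)
    ids
  })
}

serialize_alternatives <- function(step) {
  paste(vapply(step, paste, "", collapse = "+"), collapse = ",")
}

#' Construct a module definition
#'
#' @param module_id unique module identifier (e.g. `"M00165"` or
#'   `"CUST_IAM"`).
#' @param name human-readable module name.
#' @param category one of `carbon_fixation`, `nitrogen`, `sulfur`,
#'   `phosphorus`, `cobalamin`, `auxin`, `ethylene`.
#' @param steps the ordered reaction steps: either a character vector of
#'   expressions in the catalog grammar (e.g. `"K00001,K00003+K00004"`), or
#'   a list where each step is a list of character vectors (one vector per
#'   alternative complex).
#' @param keys key-enzyme clauses, same grammar as `steps`; may be empty.
#'   Every key identifier must also occur in some step.
#' @return an object of class `module_def`.
#' @export
#' @examples
#' m <- module_definition("CUST_X", "toy", "nitrogen",
#'                        steps = c("nasA,narB", "nirA"), keys = "nirA")
#' module_completeness(m, c("narB", "nirA"))
module_definition <- function(module_id, name, category, steps, keys = list()) {
  if (!is_string(module_id) || !nzchar(module_id))
    stop_field("module_id", "must be a non-empty string")
  if (!is_string(name)) stop_field("name", "must be a string")
  if (!is_string(category) || !(category %in% MODULE_CATEGORIES))
    stop_field("category", paste("must be one of:",
                                 paste(MODULE_CATEGORIES, collapse = ", ")))
  norm <- function(x, what) {
    if (is.character(x)) x <- lapply(x, parse_alternatives)
    if (!is.list(x)) stop_field(what, "must be a list or character vector")
    lapply(x, function(el) {
      if (is.character(el) && length(el) == 1L) el <- parse_alternatives(el)
      if (!is.list(el)) el <- list(el)
      lapply(el, function(ids) {
        ids <- as.character(ids)
        if (length(ids) == 0L || any(!nzchar(ids)))
          stop_field(what, "identifiers must be non-empty strings")
        ids
      })
    })
  }
  def <- structure(
    list(module_id = module_id, name = name, category = category,
         steps = norm(steps, "steps"), keys = norm(keys, "keys")),
    class = "module_def"
  )
  validate_module(def)
  def
}

#' All identifiers used by a module's steps
#'
#' @param definition a `module_def`.
#' @return character vector of unique identifiers.
#' @export
module_identifiers <- function(definition) {
  unique(unlist(definition$steps, use.names = FALSE))
}

validate_module <- function(def) {
  if (length(def$steps) < 1L)
    stop(sprintf("module '%s': must have at least one step", def$module_id),
         call. = FALSE)
  ids <- module_identifiers(def)
  key_ids <- unique(unlist(def$keys, use.names = FALSE))
  orphan <- setdiff(key_ids, ids)
  if (length(orphan))
    stop(sprintf("module '%s': key identifier(s) absent from steps: %s",
                 def$module_id, paste(orphan, collapse = ", ")),
         call. = FALSE)
  invisible(def)
}

#' @export
print.module_def <- function(x, ...) {
  cat(sprintf("<module %s [%s] %s>\n", x$module_id, x$category, x$name))
  for (i in seq_along(x$steps))
    cat(sprintf("  step %d: %s\n", i, serialize_alternatives(x$steps[[i]])))
  for (k in x$keys)
    cat(sprintf("  key:    %s\n", serialize_alternatives(k)))
  invisible(x)
}

#' @export
print.module_catalog <- function(x, ...) {
  cat(sprintf("<module catalog: %d modules>\n", length(x)))
  tab <- table(vapply(x, function(m) m$category, ""))
  for (nm in names(tab)) cat(sprintf("  %-15s %d\n", nm, tab[[nm]]))
  invisible(x)
}

new_catalog <- function(modules) {
  names(modules) <- vapply(modules, function(m) m$module_id, "")
  structure(modules, class = "module_catalog")
}

#' Validate a module catalog
#'
#' Checks id uniqueness and every module's internal invariants (at least
#' one step; key identifiers all present in steps).
#'
#' @param catalog a `module_catalog`.
#' @return the catalog, invisibly; errors describe the first violation.
#' @export
validate_catalog <- function(catalog) {
  ids <- vapply(catalog, function(m) m$module_id, "")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate module_id: %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  for (m in catalog) validate_module(m)
  invisible(catalog)
}

#' Parse a catalog from text
#'
#' Parses the plain-text module format (see the package vignette for the
#' grammar). Errors report the offending line number.
#'
#' @param text a single string, a character vector of lines, or a path to a
#'   file.
#' @return a `module_catalog`.
#' @export
parse_catalog <- function(text) {
  if (is_string(text) && file.exists(text)) text <- readLines(text)
  if (is_string(text)) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub("#.*$", "", text)
  modules <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    module_definition(cur$id, cur$name, cur$category, cur$steps, cur$keys)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    toks <- strsplit(ln, "[ \t]+")[[1]]
    kw <- toupper(toks[[1]])
    if (kw == "MODULE") {
      if (length(toks) < 3L)
        stop(sprintf("line %d: MODULE needs <id> <category> [name]", i),
             call. = FALSE)
      m <- flush(cur)
      if (!is.null(m)) modules[[length(modules) + 1L]] <- m
      cur <- list(id = toks[[2]], category = toks[[3]],
                  name = if (length(toks) > 3L)
                    paste(toks[-(1:3)], collapse = " ") else toks[[2]],
                  steps = list(), keys = list())
    } else if (kw %in% c("STEP", "KEY")) {
      if (is.null(cur))
        stop(sprintf("line %d: %s outside a MODULE block", i, kw), call. = FALSE)
      if (length(toks) != 2L)
        stop(sprintf("line %d: %s needs exactly one expression", i, kw),
             call. = FALSE)
      alts <- tryCatch(parse_alternatives(toks[[2]]),
                       error = function(e)
                         stop(sprintf("line %d: %s", i, conditionMessage(e)),
                              call. = FALSE))
      slot <- if (kw == "STEP") "steps" else "keys"
      cur[[slot]][[length(cur[[slot]]) + 1L]] <- alts
    } else {
      stop(sprintf("line %d: unknown keyword '%s'", i, toks[[1]]), call. = FALSE)
    }
  }
  m <- flush(cur)
  if (!is.null(m)) modules[[length(modules) + 1L]] <- m
  catalog <- new_catalog(modules)
  validate_catalog(catalog)
  catalog
}

#' Serialize a catalog to its text format
#'
#' `parse_catalog(serialize_catalog(x))` round-trips losslessly.
#'
#' @param catalog a `module_catalog`.
#' @param path optional file path; when given the text is written there.
#' @return the catalog text as a single string (invisibly when `path` is
#'   given).
#' @export
serialize_catalog <- function(catalog, path = NULL) {
  blocks <- vapply(catalog, function(m) {
    lines <- c(sprintf("MODULE %s %s %s", m$module_id, m$category, m$name),
               vapply(m$steps, function(s) paste("STEP", serialize_alternatives(s)), ""),
               vapply(m$keys, function(k) paste("KEY", serialize_alternatives(k)), ""))
    paste(lines, collapse = "\n")
  }, "")
  out <- paste(blocks, collapse = "\n\n")
  if (nzchar(out)) out <- paste0(out, "\n")
  if (!is.null(path)) {
    writeLines(out, path, sep = "")
    return(invisible(out))
  }
  out
}

#' Export a catalog as JSON
#'
#' @param catalog a `module_catalog`.
#' @param path optional output file.
#' @return JSON string (invisibly when `path` is given).
#' @export
catalog_to_json <- function(catalog, path = NULL) {
  x <- lapply(unclass(catalog), function(m)
    list(module_id = m$module_id, name = m$name, category = m$category,
         steps = m$steps, keys = m$keys))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' The shipped module catalog
#'
#' Returns the catalog of metabolic gene sets bundled with the package:
#' the six prokaryotic carbon-fixation modules (Wood-Ljungdahl M00377,
#' reductive TCA M00173, HP-HB M00375, 3-hydroxypropionate M00376, DC-HB
#' M00374, Calvin-Benson-Bassham M00165), assimilatory sulfate reduction
#' (M00176), and custom modules for nitrate reduction (assimilatory and
#' dissimilatory), denitrification, nitrification, nitrogen fixation,
#' taurine utilisation, sulfide/sulfite oxidation, the SOX system, alkaline
#' phosphatase, cobalamin biosynthesis (aerobic/anaerobic), pseudocobalamin
#' remodelling, DMB synthesis, cobalamin transport and dependence, the four
#' auxin (IAA) biosynthesis routes, and ACC deaminase.
#'
#' Key enzymes follow the literature conventions for each pathway, e.g. the
#' ATP-citrate lyase complex `aclA+aclB` for the reductive TCA cycle and
#' malonyl-CoA reductase `mcr` for the 3-hydroxypropionate cycle. Custom
#' entries are a curated reconstruction from published gene lists, not an
#' official KEGG export; the text format makes them easy to replace.
#'
#' @return a validated `module_catalog`.
#' @export
#' @examples
#' cat <- builtin_catalog()
#' names(cat)[vapply(cat, function(m) m$category, "") == "carbon_fixation"]
builtin_catalog <- function() {
  path <- system.file("extdata", "builtin_modules.txt", package = "phycofunc",
                      mustWork = TRUE)
  parse_catalog(path)
}

#' Gene-symbol to KO-number alias table
#'
#' A partial mapping from the gene symbols used in the shipped catalog to
#' KEGG Orthology K-numbers, for matching symbol-based catalogs against
#' K-number annotations. Matching is exact-string after alias resolution;
#' symbols without a confident K-number are left unmapped.
#'
#' @return named character vector (names = symbols, values = K-numbers).
#' @export
builtin_aliases <- function() {
  c(nasA = "K00372", narB = "K00367", nirA = "K00366",
    narG = "K00370", narH = "K00371", narI = "K00374",
    napA = "K02567", napB = "K02568",
    nirB = "K00362", nirD = "K00363", nrfA = "K03385", nrfH = "K15876",
    nirK = "K00368", nirS = "K15864", norB = "K04561", norC = "K02305",
    nosZ = "K00376",
    amoA = "K10944", amoB = "K10945", amoC = "K10946",
    nifH = "K02588", nifD = "K02586", nifK = "K02591",
    tauA = "K15551", tauB = "K10831", tauC = "K15552", tauD = "K03119",
    dsrA = "K11180", dsrB = "K11181",
    soxA = "K17222", soxX = "K17223", soxB = "K17224",
    soxY = "K17226", soxZ = "K17227",
    SUOX = "K00387",
    phoA = "K01077", phoD = "K01113",
    acdS = "K01505", btuB = "K16092",
    metH = "K00548", metE = "K00549", bluB = "K02226",
    cbiB = "K02227", cbiZ = "K08669",
    iaaM = "K00466", iaaH = "K01426", ipdC = "K04103",
    ddc = "K01593", tynA = "K00276", aldH = "K00128", nit = "K01501",
    mcr = "K14468")
}

#' Apply an alias table to identifiers or a catalog
#'
#' Replaces every identifier found in `aliases` by its mapped value;
#' identifiers without an alias are kept verbatim. Works on a character
#' vector (e.g. a genome's KO set) or a whole `module_catalog`.
#'
#' @param x character vector or `module_catalog`.
#' @param aliases named character vector, see [builtin_aliases()].
#' @return object of the same shape with identifiers substituted.
#' @export
apply_aliases <- function(x, aliases = builtin_aliases()) {
  sub1 <- function(ids) {
    hit <- ids %in% names(aliases)
    ids[hit] <- unname(aliases[ids[hit]])
    ids
  }
  if (is.character(x)) return(sub1(x))
  if (inherits(x, "module_def")) {
    x$steps <- lapply(x$steps, function(s) lapply(s, sub1))
    x$keys <- lapply(x$keys, function(k) lapply(k, sub1))
    return(x)
  }
  if (inherits(x, "module_catalog"))
    return(new_catalog(lapply(unclass(x), apply_aliases, aliases = aliases)))
  stop_field("x", "must be a character vector, module_def or module_catalog")
}
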