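# Categorised clinical code lists: the registry that drives every
# phenotyping rule. Codes are Read-code style string tokens; categories are
# the semantic roles a code can play in a case definition.

#' Code-list categories
#'
#' The recognised semantic categories for clinical codes, in classification
#' precedence order: diagnosis tiers first, then treatment classes, then the
#' remaining flag categories. [classify_code()] returns the first matching
#' category in this order when a code appears on several lists.
#'
#' @return Character vector of category tags.
#' @export
#' @examples
#' code_categories()
code_categories <- function() {
  c("CORE_DX", "LIKELY_DX", "POSSIBLE_DX",
    "TOPICAL_STEROID", "TCI", "EMOLLIENT", "TOPICAL_ANTIINFECTIVE",
    "SYSTEMIC", "PHOTOTHERAPY",
    "EXCLUSION", "DERM_CONSULT", "ATOPY", "PROCEDURE")
}

#' Treatment categories
#'
#' The subset of [code_categories()] that counts as an eczema-related
#' therapy when tallying treatment dates: emollients (topical skin
#' preparations), topical steroids, topical calcineurin inhibitors,
#' topical anti-infectives, systemic immunomodulators and phototherapy,
#' following British National Formulary-style groupings.
#'
#' @return Character vector of category tags.
#' @export
treatment_categories <- function() {
  c("EMOLLIENT", "TOPICAL_STEROID", "TCI", "TOPICAL_ANTIINFECTIVE",
    "SYSTEMIC", "PHOTOTHERAPY")
}

#' Categories specific enough to indicate eczema therapy
#'
#' Topical steroids and topical calcineurin inhibitors, the drug classes
#' used by the stricter case-definition variants.
#'
#' @return Character vector of category tags.
#' @export
specific_treatment_categories <- function() c("TOPICAL_STEROID", "TCI")

# Typographical variants of the core codes occasionally seen on input;
# mapped to canonical forms before any matching.
.code_aliases <- c("M1120.0" = "M112.00", "M11400" = "M114.00")

#' Canonicalise clinical codes
#'
#' Trims surrounding whitespace and maps known typographical variants of the
#' core eczema codes (`M1120.0`, `M11400`) to their canonical forms
#' (`M112.00`, `M114.00`).
#'
#' @param code Character vector of code tokens.
#' @return Character vector of canonical codes.
#' @export
#' @examples
#' canonicalise_code(c(" M111.00", "M1120.0"))
canonicalise_code <- function(code) {
  code <- trimws(code)
  hit <- code %in% names(.code_aliases)
  code[hit] <- .code_aliases[code[hit]]
  code
}

new_codelist <- function(code, description, category, provenance = "in-memory") {
  stopifnot(all(category %in% code_categories()))
  out <- data.frame(
    code = as.character(code),
    description = as.character(description),
    category = as.character(category),
    stringsAsFactors = FALSE
  )
  # uniqueness within category
  if (anyDuplicated(out[, c("code", "category")]) > 0L) {
    out <- out[!duplicated(out[, c("code", "category")]), , drop = FALSE]
  }
  attr(out, "provenance") <- provenance
  class(out) <- c("codelist", "data.frame")
  out
}

#' Built-in core eczema diagnosis codes
#'
#' The five Read codes most commonly and specifically used for atopic
#' eczema in UK primary care, shipped with the package: M111.00 (atopic
#' dermatitis/eczema), M112.00 (infantile eczema), M113.00 (flexural
#' eczema), M114.00 (allergic/intrinsic eczema) and M12z100 (eczema not
#' otherwise specified). All other code categories (wider diagnosis tiers,
#' treatment classes, exclusions, consults, atopy) are supplied by the user
#' as code-list files.
#'
#' @return A `codelist` with five `CORE_DX` entries.
#' @export
#' @examples
#' builtin_core_codes()
builtin_core_codes <- function() {
  new_codelist(
    code = c("M111.00", "M112.00", "M113.00", "M114.00", "M12z100"),
    description = c(
      "Atopic dermatitis/eczema",
      "Infantile eczema",
      "Flexural eczema",
      "Allergic/intrinsic eczema",
      "Eczema not otherwise specified"
    ),
    category = "CORE_DX",
    provenance = "builtin"
  )
}

#' Load a code list from a delimited text file
#'
#' Reads a two- or three-column delimited file (`code,description[,category]`,
#' comma or tab auto-detected, optional header row, UTF-8). When the file has
#' no category column, `category` supplies the tag for every entry; a category
#' column in the file takes precedence. Duplicate codes within a category
#' collapse to the first entry with a warning.
#'
#' @param path Path to the file.
#' @param category Default category tag for entries without one.
#' @return A `codelist`.
#' @export
load_codelist <- function(path, category = NULL) {
  if (!file.exists(path)) {
    stop("code-list file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 0L]
  if (length(lines) == 0L) {
    warning("empty code-list file: ", path, call. = FALSE)
    return(new_codelist(character(), character(), character(), provenance = path))
  }
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  # strip optional CSV quoting around fields
  fields <- lapply(fields, function(f) gsub('^"|"$', "", trimws(f)))
  # optional header: first row whose first cell is literally "code"
  start <- 1L
  if (tolower(trimws(fields[[1]][1])) == "code") start <- 2L
  if (start > length(fields)) {
    warning("empty code-list file: ", path, call. = FALSE)
    return(new_codelist(character(), character(), character(), provenance = path))
  }
  rows <- fields[start:length(fields)]
  line_no <- seq(start, length(fields))
  code <- vapply(rows, function(f) trimws(f[1]), character(1))
  bad <- which(!nzchar(code))
  if (length(bad) > 0L) {
    stop("blank code field in ", path, " at line ", line_no[bad[1]],
         call. = FALSE)
  }
  desc <- vapply(rows, function(f) if (length(f) >= 2) trimws(f[2]) else "",
                 character(1))
  cat_col <- vapply(rows, function(f) if (length(f) >= 3) trimws(f[3]) else NA_character_,
                    character(1))
  cat_out <- ifelse(is.na(cat_col) | !nzchar(cat_col), category %||% NA_character_, cat_col)
  if (anyNA(cat_out)) {
    stop("no category for some entries in ", path,
         " and no default `category` given", call. = FALSE)
  }
  unknown <- setdiff(unique(cat_out), code_categories())
  if (length(unknown) > 0L) {
    stop("unknown code categories in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  code <- canonicalise_code(code)
  dup <- duplicated(paste(code, cat_out, sep = "\r"))
  if (any(dup)) {
    warning(sum(dup), " duplicate code(s) collapsed in ", path, call. = FALSE)
  }
  new_codelist(code[!dup], desc[!dup], cat_out[!dup], provenance = path)
}

#' Write a code list to a CSV file
#'
#' @param x A `codelist` or code-list collection.
#' @param path Output path; written as `code,description,category` with header.
#' @return `path`, invisibly.
#' @export
write_codelist <- function(x, path) {
  df <- as.data.frame(x)[, c("code", "description", "category")]
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Combine code lists into one registry
#'
#' Binds several `codelist` objects into a single collection, checking the
#' tier-nesting and exclusion invariants: when the wider diagnosis tiers are
#' present, `CORE_DX` codes must also appear in `LIKELY_DX` and `LIKELY_DX`
#' in `POSSIBLE_DX`; no code may be both a diagnosis and an exclusion.
#'
#' @param ... `codelist` objects (or a single list of them).
#' @return A `codelist` collection (stacked entries).
#' @export
codelist_collection <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "codelist") && is.list(parts[[1]])) {
    parts <- parts[[1]]
  }
  stopifnot(all(vapply(parts, inherits, logical(1), "codelist")))
  all <- do.call(rbind, lapply(parts, as.data.frame))
  cl <- new_codelist(all$code, all$description, all$category,
                     provenance = "collection")
  .check_tier_nesting(cl)
  dx_cats <- c("CORE_DX", "LIKELY_DX", "POSSIBLE_DX")
  both <- intersect(cl$code[cl$category %in% dx_cats],
                    cl$code[cl$category == "EXCLUSION"])
  if (length(both) > 0L) {
    stop("code(s) in both a diagnosis tier and EXCLUSION: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  cl
}

.check_tier_nesting <- function(cl) {
  core <- cl$code[cl$category == "CORE_DX"]
  likely <- cl$code[cl$category == "LIKELY_DX"]
  possible <- cl$code[cl$category == "POSSIBLE_DX"]
  if (length(likely) > 0L && length(core) > 0L && !all(core %in% likely)) {
    stop("tier nesting violated: CORE_DX codes missing from LIKELY_DX",
         call. = FALSE)
  }
  if (length(possible) > 0L && length(likely) > 0L && !all(likely %in% possible)) {
    stop("tier nesting violated: LIKELY_DX codes missing from POSSIBLE_DX",
         call. = FALSE)
  }
  invisible(cl)
}

#' Classify codes against a code-list collection
#'
#' Maps each code to the category of the first matching list under the
#' documented precedence (diagnosis tiers before treatment classes before
#' flag categories; see [code_categories()]), or `NA` when unmatched.
#' Matching is exact string equality after whitespace trimming and alias
#' canonicalisation; an optional prefix mode matches a code when a listed
#' code is a prefix of it (for hierarchical Read-code lists), off by default.
#'
#' @param code Character vector of codes to classify.
#' @param lists A `codelist` or collection.
#' @param prefix Logical; enable prefix matching.
#' @return Character vector of category tags (`NA` for unmatched codes).
#' @export
#' @examples
#' classify_code("M111.00", builtin_core_codes())
classify_code <- function(code, lists, prefix = FALSE) {
  code <- canonicalise_code(code)
  cat_rank <- match(lists$category, code_categories())
  ord <- order(cat_rank)
  lcode <- lists$code[ord]
  lcat <- lists$category[ord]
  if (!prefix) {
    idx <- match(code, lcode)
    out <- ifelse(is.na(idx), NA_character_, lcat[idx])
  } else {
    out <- vapply(code, function(cd) {
      hit <- which(startsWith(cd, lcode))
      if (length(hit) == 0L) NA_character_ else lcat[hit[1]]
    }, character(1), USE.NAMES = FALSE)
  }
  out
}

#' @export
print.codelist <- function(x, ...) {
  cat("<codelist> ", nrow(x), " entries (",
      paste(unique(x$category), collapse = ", "), ")\n", sep = "")
  print(as.data.frame(head(x, 10)), row.names = FALSE)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
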