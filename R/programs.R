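#' Neurogenic programs
#'
#' A neurogenic program is the proportional occurrence of each of the seven
#' progenitor lineages during corticogenesis (fractions summing to 1).
#' Built-in programs correspond to the best-fit proportions for mouse
#' (10/80/10 on lineages 1-3), human (0/20/40/10/10/10/10), marmoset
#' (0/60/40) and opossum (80/10/10).
#'
#' @param x one of: a character name of a built-in program (`"mouse"`,
#'   `"human"`, `"marmoset"`, `"opossum"`), a numeric vector of length 7 of
#'   percentages (summing to 100 +/- 0.1) or fractions (summing to 1), or a
#'   path to a one-row CSV file with columns `lineage1`..`lineage7` holding
#'   percentages.
#' @return An object of class `"neurogenic_program"`: a named numeric
#'   vector of 7 fractions summing to 1.
#' @examples
#' neurogenic_program("human")
#' neurogenic_program(c(10, 80, 10, 0, 0, 0, 0))
#' @export
neurogenic_program <- function(x) {
  if (inherits(x, "neurogenic_program")) return(x)
  if (is.character(x) && length(x) == 1L) {
    builtin <- builtin_programs()
    if (x %in% rownames(builtin)) {
      p <- builtin[x, ]
    } else if (file.exists(x)) {
      tab <- utils::read.csv(x, check.names = FALSE)
      cols <- paste0("lineage", 1:7)
      if (!all(cols %in% names(tab))) {
        stop("program file must have columns lineage1..lineage7",
             call. = FALSE)
      }
      p <- as.numeric(tab[1L, cols])
    } else {
      stop("unknown program '", x, "' (not a built-in name or file)",
           call. = FALSE)
    }
  } else if (is.numeric(x)) {
    if (length(x) != 7L) stop("a program needs 7 proportions", call. = FALSE)
    p <- as.numeric(x)
  } else {
    stop("cannot interpret 'x' as a neurogenic program", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("program proportions must be finite and non-negative",
         call. = FALSE)
  }
  s <- sum(p)
  if (abs(s - 1) < 1e-9) {
    # already fractions
  } else if (abs(s - 100) <= 0.1) {
    p <- p / 100
  } else {
    stop("program proportions must sum to 1 or to 100 (+/- 0.1); got ",
         format(s), call. = FALSE)
  }
  p <- p / sum(p)
  names(p) <- paste0("lineage", 1:7)
  structure(p, class = "neurogenic_program")
}

#' @export
print.neurogenic_program <- function(x, ...) {
  cat("<neurogenic program> percent occurrence per lineage:\n")
  print(round(100 * unclass(x), 2))
  invisible(x)
}

#' Built-in lineage proportions per taxon
#'
#' The best-fit proportional occurrences (percent) of lineages 1-7 for the
#' 17 reference species, as shipped in
#' `system.file("extdata", "lineage_programs.csv", package = "cortigen")`.
#' Mouse-type programs place all weight on lineages 1-3; human-type
#' programs place none on lineage 1 and 40% on the proliferative
#' lineages 4-7.
#'
#' @return A numeric matrix (rows = taxa, columns `lineage1`..`lineage7`)
#'   of fractions summing to 1 per row.
#' @export
builtin_programs <- function() {
  path <- system.file("extdata", "lineage_programs.csv",
                      package = "cortigen", mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(tab[, paste0("lineage", 1:7)]) / 100
  rownames(m) <- tolower(tab$taxon)
  m
}

#' Species-specific program lookup
#'
#' @param species species name matched (case-insensitively) against the
#'   shipped program table.
#' @return A [neurogenic_program()].
#' @export
species_program <- function(species) {
  m <- builtin_programs()
  key <- tolower(species)
  if (!key %in% rownames(m)) {
    stop("no built-in program for species '", species, "'", call. = FALSE)
  }
  neurogenic_program(as.numeric(m[key, ]))
}

validate_program <- function(program) {
  program <- neurogenic_program(program)
  if (abs(sum(program) - 1) > 1e-9) {
    stop("program proportions must sum to 1", call. = FALSE)
  }
  program
}
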