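#' Construct a validated trait matrix
#'
#' A trait matrix maps each taxon to one discrete state drawn from an
#' ordered state alphabet.  Missing observations must be coded explicitly
#' as `"?"`; any other label outside the alphabet is an error.
#'
#' @param states named character vector: `names(states)` are taxa, values
#'   are state labels.
#' @param alphabet ordered character vector of admissible state labels.
#' @param name character scalar naming the character (used in reports).
#' @return an object of class `"trait_matrix"`: a list with elements
#'   `states`, `alphabet`, `name`.
#' @export
#' @examples
#' trait_matrix(c(A = "annual", B = "shrub"),
#'              alphabet = c("annual", "herbaceous_perennial",
#'                           "suffrutescent_perennial", "shrub"))
trait_matrix <- function(states, alphabet, name = "trait") {
  states <- unlist(states)
  if (is.null(names(states)) || any(!nzchar(names(states))))
    stop("every state must be named by its taxon")
  dup <- names(states)[duplicated(names(states))]
  if (length(dup))
    stop("duplicate taxon/taxa: ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(alphabet) || any(!nzchar(alphabet)))
    stop("state alphabet must be unique, non-empty labels")
  taxa <- names(states)
  states <- as.character(states)
  names(states) <- taxa
  bad <- which(!(states %in% c(alphabet, "?")))
  if (length(bad))
    stop("state label(s) not in alphabet: ",
         paste(sprintf("taxon '%s' has state '%s'",
                       names(states)[bad], states[bad]), collapse = "; "))
  structure(list(states = states, alphabet = as.character(alphabet),
                 name = name),
            class = "trait_matrix")
}

#' Read a taxon-state trait table
#'
#' Reads a delimited table with a header containing columns `taxon` and
#' `state` (TSV by default; comma-separated when the file ends in `.csv`)
#' and validates it against a state alphabet.
#'
#' @param path path to the table.
#' @param alphabet ordered character vector of admissible state labels.
#' @param name character name (defaults to the file base name).
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return a [trait_matrix()].
#' @export
read_traits <- function(path, alphabet, name = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  if (!all(c("taxon", "state") %in% names(df)))
    stop("trait table must have header columns 'taxon' and 'state'")
  dup <- which(duplicated(df$taxon))
  if (length(dup))
    stop("duplicate taxon at row(s) ", paste(dup, collapse = ", "), ": ",
         paste(unique(df$taxon[dup]), collapse = ", "))
  bad <- which(!(df$state %in% c(alphabet, "?")))
  if (length(bad))
    stop("unknown state label at row(s) ",
         paste(sprintf("%d (taxon '%s', state '%s')",
                       bad, df$taxon[bad], df$state[bad]), collapse = "; "))
  trait_matrix(stats::setNames(df$state, df$taxon), alphabet,
               name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a trait matrix as a TSV table
#'
#' @param x a `trait_matrix`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_traits <- function(x, path) {
  stopifnot(inherits(x, "trait_matrix"))
  utils::write.table(
    data.frame(taxon = names(x$states), state = unname(x$states)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("Trait matrix '%s': %d taxa, alphabet {%s}\n",
              x$name, length(x$states), paste(x$alphabet, collapse = ", ")))
  invisible(x)
}

# Tip partial-likelihood rows for a tree: indicator rows for observed
# states, all-ones rows for "?".  Errors if any tip lacks an observation.
.tip_partials <- function(tree, traits) {
  stopifnot(inherits(traits, "trait_matrix"))
  tips <- tree$tip.label
  miss <- setdiff(tips, names(traits$states))
  if (length(miss))
    stop("tip(s) without trait observation: ", paste(miss, collapse = ", "))
  k <- length(traits$alphabet)
  ntot <- length(tips) + tree$Nnode
  part <- matrix(1, ntot, k)
  st <- traits$states[tips]
  obs <- st != "?"
  idx <- match(st[obs], traits$alphabet)
  rows <- which(obs)
  part[rows, ] <- 0
  part[cbind(rows, idx)] <- 1
  part
}
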