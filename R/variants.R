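# Mutation-set accounting for engineered hydrolase variants.
#
# Variants are stored as explicit sets of point mutations relative to the
# wild-type sequence (1-based positions in the parent numbering), never as
# diffs against another variant, so reversions are expressed by dropping or
# replacing the parental mutation.

AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Parse a point-mutation token
#'
#' Tokens use the conventional \code{<wt><position><new>} notation, e.g.
#' \code{"L93F"} for leucine 93 to phenylalanine.
#'
#' @param token character scalar.
#' @return object of class \code{pk_mutation}: list with \code{wt},
#'   \code{pos}, \code{new}.
#' @examples
#' parse_mutation("L93F")
#' @export
parse_mutation <- function(token) {
  if (!is.character(token) || length(token) != 1L || is.na(token))
    stop("mutation token must be a single character string", call. = FALSE)
  token <- trimws(token)
  if (!grepl("^[A-Za-z][0-9]+[A-Za-z]$", token))
    stop(sprintf("malformed mutation token '%s' (expected e.g. 'L93F')", token),
         call. = FALSE)
  wt <- toupper(substr(token, 1L, 1L))
  new <- toupper(substr(token, nchar(token), nchar(token)))
  pos <- as.integer(substr(token, 2L, nchar(token) - 1L))
  if (!(wt %in% AA1) || !(new %in% AA1))
    stop(sprintf("'%s': residue codes must be one of the 20 amino acids", token),
         call. = FALSE)
  if (wt == new)
    stop(sprintf("'%s': silent mutation (wild-type and new residue identical)",
                 token), call. = FALSE)
  if (pos < 1L) stop("mutation position must be >= 1", call. = FALSE)
  structure(list(wt = wt, pos = pos, new = new), class = "pk_mutation")
}

#' @export
format.pk_mutation <- function(x, ...) paste0(x$wt, x$pos, x$new)

#' @export
print.pk_mutation <- function(x, ...) {
  cat("<mutation>", format(x), "\n")
  invisible(x)
}

#' Define a named variant from mutation tokens
#'
#' @param name variant label, e.g. \code{"R2M2"}.
#' @param mutations character vector of mutation tokens (or a single
#'   semicolon-separated string), or a list of \code{pk_mutation}.
#' @param parent optional parent variant label.
#' @param round engineering round (integer, 0-4 in typical campaigns;
#'   not restricted).
#' @return object of class \code{pk_variant}.
#' @export
variant_spec <- function(name, mutations = character(), parent = NA_character_,
                         round = NA_integer_) {
  if (is.character(mutations)) {
    mutations <- unlist(strsplit(mutations, "[;/]"))
    mutations <- trimws(mutations[nzchar(trimws(mutations))])
    mutations <- lapply(mutations, parse_mutation)
  }
  stopifnot(all(vapply(mutations, inherits, TRUE, "pk_mutation")))
  pos <- vapply(mutations, function(m) m$pos, 1L)
  if (anyDuplicated(pos))
    stop(sprintf("variant '%s': two mutations share position %d",
                 name, pos[duplicated(pos)][1L]), call. = FALSE)
  mutations <- mutations[order(pos)]
  structure(list(name = as.character(name), mutations = mutations,
                 parent = parent, round = round),
            class = "pk_variant")
}

#' @export
format.pk_variant <- function(x, ...) {
  paste0(x$name, " [", length(x$mutations), " mutations: ",
         paste(vapply(x$mutations, format, ""), collapse = ";"), "]")
}

#' @export
print.pk_variant <- function(x, ...) {
  cat("<variant>", format(x), "\n")
  invisible(x)
}

#' Apply a variant's mutations to a sequence
#'
#' Every mutation's wild-type residue must match the input sequence at its
#' position; mismatches are reported with the position and the expected and
#' found residues.
#'
#' @param sequence amino-acid string (one-letter codes).
#' @param variant \code{pk_variant} (or list of \code{pk_mutation}).
#' @return mutated amino-acid string.
#' @export
apply_mutations <- function(sequence, variant) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  muts <- if (inherits(variant, "pk_variant")) variant$mutations else variant
  chars <- strsplit(sequence, "")[[1]]
  for (m in muts) {
    if (m$pos > length(chars))
      stop(sprintf("mutation %s: position %d beyond sequence length %d",
                   format(m), m$pos, length(chars)), call. = FALSE)
    if (chars[m$pos] != m$wt)
      stop(sprintf("mutation %s: expected %s at position %d, found %s",
                   format(m), m$wt, m$pos, chars[m$pos]), call. = FALSE)
    chars[m$pos] <- m$new
  }
  paste(chars, collapse = "")
}

#' Invert a mutation set
#'
#' @param variant \code{pk_variant}.
#' @return \code{pk_variant} with every mutation reversed (new -> wt).
#' @export
invert_variant <- function(variant) {
  stopifnot(inherits(variant, "pk_variant"))
  inv <- lapply(variant$mutations, function(m)
    structure(list(wt = m$new, pos = m$pos, new = m$wt), class = "pk_mutation"))
  structure(list(name = paste0(variant$name, "_inv"), mutations = inv,
                 parent = variant$name, round = variant$round),
            class = "pk_variant")
}

#' Side-chain formal charge model
#'
#' At pH 8 the side chains of Asp and Glu carry -1, Lys and Arg +1, and His
#' is treated as neutral (pKa ~ 6); Cys and Tyr are counted neutral as well.
#' Termini are excluded. The map can be overridden, e.g. to count His +1 at
#' acidic pH.
#'
#' @param pH solution pH (recorded; the default map corresponds to pH 8).
#' @param overrides named integer vector of per-residue charges to override.
#' @return object of class \code{pk_charge_model}.
#' @export
charge_model <- function(pH = 8.0, overrides = NULL) {
  charges <- setNames(integer(20), AA1)
  charges[c("D", "E")] <- -1L
  charges[c("K", "R")] <- +1L
  if (!is.null(overrides)) {
    stopifnot(all(names(overrides) %in% AA1),
              all(overrides %in% c(-1L, 0L, 1L)))
    charges[names(overrides)] <- as.integer(overrides)
  }
  structure(list(pH = pH, charges = charges), class = "pk_charge_model")
}

#' Net formal-charge change of a variant
#'
#' Sum over mutations of charge(new residue) - charge(wild-type residue)
#' under the side-chain formal charge model. Additive over disjoint
#' mutation sets; a variant plus its full reversion sums to zero.
#'
#' @param variant \code{pk_variant}.
#' @param model \code{pk_charge_model}; default pH 8.
#' @return integer charge delta in elementary charges.
#' @examples
#' net_charge_delta(variant_spec("x", "E148K"))  # -1 -> +1, delta +2
#' @export
net_charge_delta <- function(variant, model = charge_model()) {
  stopifnot(inherits(variant, "pk_variant"), inherits(model, "pk_charge_model"))
  if (length(variant$mutations) == 0L) return(0L)
  ch <- model$charges
  sum(vapply(variant$mutations, function(m) ch[[m$new]] - ch[[m$wt]], 1L))
}

#' Read a variant table
#'
#' CSV with columns \code{name,parent,round,mutations}; the mutations column
#' holds semicolon-separated tokens. A packaged table of the variants used
#' in this package's worked examples is available via
#' \code{system.file("extdata", "phl7_variants.csv", package = "petkit")}.
#'
#' @param path CSV file path.
#' @return named list of \code{pk_variant}.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "parent", "round", "mutations")
  if (!all(need %in% names(df)))
    stop("variant table must have columns name,parent,round,mutations",
         call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    variant_spec(df$name[i], df$mutations[i],
                 parent = if (is.na(df$parent[i]) || df$parent[i] == "")
                   NA_character_ else df$parent[i],
                 round = as.integer(df$round[i])))
  names(out) <- df$name
  out
}
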