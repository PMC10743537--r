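# The nicked DNA decamer duplex and its nick-adjacent units.

#' Nick map of the model decamer duplex
#'
#' Describes the nicked DNA decamer used as a model of the topoisomerase I
#' cleavage intermediate: two decanucleotide strands, with a single-strand
#' break (nick) in strand 1 between units T5 and G6.  The
#' "nick-adjacent" set defaults to the two base pairs on each face of the
#' nick -- the flanking pairs G6-C15 and T5-A16 plus the adjacent pairs
#' T7-A14 and T4-A17 -- i.e. units T4, T5, G6, T7 on strand 1 and A14,
#' C15, A16, A17 on strand 2.
#'
#' @param strand1 Ordered unit labels of strand 1 (contains the nick).
#' @param strand2 Ordered unit labels of strand 2.
#' @param nick_between Length-2 character vector: the two strand-1 units
#'   between which the nick lies.
#' @param nick_adjacent Unit labels counted as nick-adjacent.
#' @return An object of class `nick_map`.
#' @examples
#' nick_map()
#' @export
nick_map <- function(strand1 = c("G1", "C2", "G3", "T4", "T5",
                                 "G6", "T7", "C8", "G9", "C10"),
                     strand2 = c("G11", "C12", "G13", "A14", "C15",
                                 "A16", "A17", "C18", "G19", "C20"),
                     nick_between = c("T5", "G6"),
                     nick_adjacent = c("T4", "T5", "G6", "T7",
                                       "A14", "C15", "A16", "A17")) {
  units <- c(strand1, strand2)
  if (anyDuplicated(units)) abort("duplicated unit labels across strands")
  if (length(nick_between) != 2 || !all(nick_between %in% strand1)) {
    abort("the nick must lie between two units of strand 1")
  }
  i <- match(nick_between, strand1)
  if (i[2] != i[1] + 1) abort("nick_between must name consecutive strand-1 units")
  if (!all(nick_adjacent %in% units)) {
    abort("nick_adjacent contains labels absent from the strands")
  }
  structure(list(strand1 = strand1, strand2 = strand2,
                 nick_between = nick_between, nick_adjacent = nick_adjacent),
            class = "nick_map")
}

#' @export
print.nick_map <- function(x, ...) {
  i <- match(x$nick_between[1], x$strand1)
  s1 <- paste(append(x$strand1, "| nick |", after = i), collapse = " ")
  cat("Nicked duplex map\n",
      "  strand 1: ", s1, "\n",
      "  strand 2: ", paste(x$strand2, collapse = " "), "\n",
      "  nick-adjacent: ", paste(x$nick_adjacent, collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Read a nick map from JSON
#'
#' Expects an object with fields `strand1`, `strand2`, `nick_between`
#' and `nick_adjacent`, as written by [write_nick_map()].
#'
#' @param path Path to a JSON file.
#' @return A `nick_map` object.
#' @examples
#' read_nick_map(nmrbind_example("nick_map.json"))
#' @export
read_nick_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nick_map(strand1 = x$strand1, strand2 = x$strand2,
           nick_between = x$nick_between, nick_adjacent = x$nick_adjacent)
}

#' Write a nick map to JSON
#'
#' @param nick A `nick_map` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nick_map <- function(nick, path) {
  stopifnot(inherits(nick, "nick_map"))
  jsonlite::write_json(unclass(nick), path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
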