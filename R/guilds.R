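# Ecoguild assignment: species are reduced to four guilds via PCA of
# one-hot-encoded diet and foraging-stratum categories; the four quadrants
# of the (PC1, PC2) plane define the guilds. Only guild co-membership
# matters downstream (same-guild lineages interact), so the arbitrary but
# deterministic axis orientation is harmless.

#' @export
DIET_LEVELS <- c("invertebrates", "terrestrial vertebrates", "fishes",
                 "carrion", "fruit", "nectar", "seeds", "plants")

#' @export
FORAGE_LEVELS <- c("ground", "understory", "mid-high", "canopy", "aerial",
                   "pelagic-below-surface", "pelagic-above-surface",
                   "nonpelagic-below-surface", "nonpelagic-above-surface")

check_categories <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("species", "diet", "forage") %in% names(table)))
  bad_d <- setdiff(unique(table$diet), DIET_LEVELS)
  if (length(bad_d)) stop("unknown diet label(s): ",
                          paste(bad_d, collapse = ", "))
  bad_f <- setdiff(unique(table$forage), FORAGE_LEVELS)
  if (length(bad_f)) stop("unknown forage label(s): ",
                          paste(bad_f, collapse = ", "))
  if (anyDuplicated(table$species)) stop("duplicate species rows")
  invisible(table)
}

#' One-hot encode diet and foraging categories
#'
#' @param table data frame with columns `species`, `diet`, `forage`.
#' @return a species-by-17 binary indicator matrix (8 diet + 9 forage
#'   columns); every row sums to 2.
#' @export
encode_onehot <- function(table) {
  check_categories(table)
  M <- cbind(
    outer(table$diet, DIET_LEVELS, `==`) + 0,
    outer(table$forage, FORAGE_LEVELS, `==`) + 0
  )
  dimnames(M) <- list(table$species,
                      c(paste0("diet:", DIET_LEVELS),
                        paste0("forage:", FORAGE_LEVELS)))
  M
}

#' Assign species to four ecoguilds
#'
#' Runs a PCA (SVD of the column-centered indicator matrix) on one-hot
#' encoded diet and foraging categories and assigns each species to the
#' quadrant of its (PC1, PC2) scores: 1 = (+,+), 2 = (-,+), 3 = (-,-),
#' 4 = (+,-). The sign of each axis is fixed by forcing its
#' largest-magnitude loading positive; scores within `1e-12` of an axis are
#' assigned to the positive side.
#'
#' @param table data frame with columns `species`, `diet`, `forage`.
#' @return an object of class `guild_assignment`: a data frame with columns
#'   `species`, `pc1`, `pc2`, `guild`.
#' @export
assign_ecoguilds <- function(table) {
  # canonical species order makes the SVD (and hence the guilds) invariant
  # to input row order even when singular values are tied
  ord <- order(table$species)
  table <- table[ord, , drop = FALSE]
  M <- encode_onehot(table)
  if (nrow(M) < 2) stop("at least two species are required")
  Mc <- scale(M, center = TRUE, scale = FALSE)
  if (nrow(unique(M)) < 2) {
    warning("all species share one category profile; single guild")
    out <- data.frame(species = rownames(M), pc1 = 0, pc2 = 0, guild = 1L,
                      stringsAsFactors = FALSE)
    class(out) <- c("guild_assignment", "data.frame")
    return(out)
  }
  sv <- svd(Mc)
  scores <- matrix(0, nrow(M), 2)
  for (a in 1:2) {
    if (a > length(sv$d) || sv$d[a] < 1e-12) break
    s <- sv$u[, a] * sv$d[a]
    load <- sv$v[, a]
    if (load[which.max(abs(load))] < 0) s <- -s
    scores[, a] <- s
  }
  pos <- function(v) v > -1e-12  # boundary ties go to the positive side
  guild <- ifelse(pos(scores[, 1]),
                  ifelse(pos(scores[, 2]), 1L, 4L),
                  ifelse(pos(scores[, 2]), 2L, 3L))
  out <- data.frame(species = rownames(M), pc1 = scores[, 1],
                    pc2 = scores[, 2], guild = guild,
                    stringsAsFactors = FALSE)
  class(out) <- c("guild_assignment", "data.frame")
  out
}

#' Guild states as a named vector
#'
#' @param guilds a `guild_assignment`.
#' @return named character vector of guild labels, usable as Mk tip states.
#' @export
guild_states <- function(guilds) {
  setNames(as.character(guilds$guild), guilds$species)
}
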