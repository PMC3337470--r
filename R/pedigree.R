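#' Generate a mammalian-style random-mating pedigree
#'
#' Builds the discrete-generation pedigree used by the livestock
#' scenario: generation 0 is a base layer of unrelated individuals with
#' alternating sexes; each later generation draws `n_sires` males and
#' `n_sires * dams_per_sire` females without replacement from the
#' previous generation, mates them in disjoint full-sib families and
#' gives each dam `offspring_per_dam` offspring of random sex.  No
#' selection and no overlapping generations.  The default parameters
#' (10 generations, 50 sires, 10 dams per sire, 2 offspring per dam)
#' give 1000 individuals per generation and 10,000 in total.
#'
#' The base generation is sized to match the later ones
#' (`n_sires * dams_per_sire * offspring_per_dam` individuals).
#'
#' @param n_generations number of generations including the base (>= 1).
#' @param n_sires sires used per generation.
#' @param dams_per_sire dams mated to each sire.
#' @param offspring_per_dam offspring per dam.
#' @return a `pedigree`: a data.frame with columns `id`, `sire`, `dam`
#'   (0 = unknown/base), `sex` (`"M"`/`"F"`) and `generation` (0-based),
#'   parents always preceding offspring.
#' @export
generate_pedigree <- function(n_generations = 10, n_sires = 50,
                              dams_per_sire = 10, offspring_per_dam = 2) {
  stopifnot(n_generations >= 1, n_sires >= 1, dams_per_sire >= 1,
            offspring_per_dam >= 1)
  per_gen <- n_sires * dams_per_sire * offspring_per_dam
  need_m <- n_sires
  need_f <- n_sires * dams_per_sire
  if (n_generations > 1 && per_gen < need_m + need_f)
    stop("generation size ", per_gen, " cannot supply ", need_m,
         " sires and ", need_f, " dams for the next generation")

  rows <- vector("list", n_generations)
  # base layer: unrelated, alternating sexes guarantee both sexes exist
  rows[[1]] <- data.frame(
    id = seq_len(per_gen), sire = 0L, dam = 0L,
    sex = rep_len(c("M", "F"), per_gen), generation = 0L,
    stringsAsFactors = FALSE)
  next_id <- per_gen + 1L

  for (g in seq_len(n_generations - 1L)) {
    prev <- rows[[g]]
    males <- prev$id[prev$sex == "M"]
    females <- prev$id[prev$sex == "F"]
    if (length(males) < need_m || length(females) < need_f)
      stop("generation ", g - 1L, " has ", length(males), " males and ",
           length(females), " females; need ", need_m, " and ", need_f)
    sires <- sample(males)[seq_len(need_m)]
    dams <- sample(females)[seq_len(need_f)]
    sire_of_dam <- rep(sires, each = dams_per_sire)

    n_off <- need_f * offspring_per_dam
    ids <- seq.int(next_id, length.out = n_off)
    # redraw sexes until this generation can supply the next one's
    # parents (cheap except for near-infeasible family configurations)
    attempts <- 0L
    repeat {
      sex <- sample(c("M", "F"), n_off, replace = TRUE)
      if (g == n_generations - 1L ||
          (sum(sex == "M") >= need_m && sum(sex == "F") >= need_f))
        break
      attempts <- attempts + 1L
      if (attempts > 1000L)
        stop("cannot draw a sex assignment with ", need_m, " males and ",
             need_f, " females among ", n_off, " offspring")
    }
    rows[[g + 1L]] <- data.frame(
      id = ids,
      sire = rep(sire_of_dam, each = offspring_per_dam),
      dam = rep(dams, each = offspring_per_dam),
      sex = sex, generation = g, stringsAsFactors = FALSE)
    next_id <- next_id + n_off
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Read a pedigree file
#'
#' Whitespace-delimited columns `id sire dam [sex]`, one individual per
#' line, `0` marking an unknown (base) parent.  Generations are inferred
#' as `1 + max(parent generation)` (base = 0).  When the sex column is
#' absent, sexes are inferred from parental roles (sires male, dams
#' female); non-parents get an alternating fill.
#'
#' @param path file path or connection.
#' @return a `pedigree` data.frame (see [generate_pedigree()]).
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "sire", "dam", "sex")[1:4],
                           fill = TRUE, colClasses = c("integer", "integer",
                                                       "integer", "character"))
  n <- nrow(raw)
  if (anyNA(raw$id) || anyNA(raw$sire) || anyNA(raw$dam))
    stop("non-integer id/sire/dam field in pedigree file")
  dup <- which(duplicated(raw$id))
  if (length(dup))
    stop("line ", dup[1], ": duplicate id ", raw$id[dup[1]])
  seen <- integer(0)
  gen <- integer(n)
  gen_of <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    for (p in c(raw$sire[i], raw$dam[i])) {
      if (p != 0 && is.null(gen_of[[as.character(p)]]))
        stop("line ", i, ": parent ", p, " not defined on an earlier line")
    }
    pg <- c(if (raw$sire[i] != 0) gen_of[[as.character(raw$sire[i])]],
            if (raw$dam[i] != 0) gen_of[[as.character(raw$dam[i])]])
    gen[i] <- if (length(pg)) max(pg) + 1L else 0L
    assign(as.character(raw$id[i]), gen[i], envir = gen_of)
  }
  both <- intersect(raw$sire[raw$sire != 0], raw$dam[raw$dam != 0])
  if (length(both))
    stop("individual ", both[1], " appears as both sire and dam")

  sex <- raw$sex
  if (all(is.na(sex) | sex == "")) {
    sex <- rep_len(c("M", "F"), n)
    sex[raw$id %in% raw$sire] <- "M"
    sex[raw$id %in% raw$dam] <- "F"
  } else {
    sex <- toupper(substr(sex, 1, 1))
    if (any(!sex %in% c("M", "F")))
      stop("sex column must be M/F")
  }
  ped <- data.frame(id = raw$id, sire = raw$sire, dam = raw$dam,
                    sex = sex, generation = gen, stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  viol <- validate_pedigree(ped)
  if (length(viol)) stop("invalid pedigree: ", viol[1])
  ped
}

#' Write a pedigree file
#'
#' @param ped a `pedigree`.
#' @param path file path or connection.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(ped[, c("id", "sire", "dam", "sex")], path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Check pedigree invariants
#'
#' Returns a character vector of violations (empty when valid) instead of
#' throwing, so it can be used both as a guard and in fault-injection
#' tests: unique ids, parents defined before use, sires male and dams
#' female, base individuals with both parents unknown, no individual its
#' own ancestor.
#'
#' @param ped a `pedigree` data.frame.
#' @return character vector of human-readable violations.
#' @export
validate_pedigree <- function(ped) {
  v <- character(0)
  if (anyDuplicated(ped$id)) v <- c(v, "duplicate ids")
  pos <- match(ped$id, ped$id)
  for (col in c("sire", "dam")) {
    p <- ped[[col]]
    known <- p != 0
    idx <- match(p[known], ped$id)
    if (anyNA(idx)) {
      v <- c(v, paste("unknown", col, "id"))
    } else if (any(idx >= which(known))) {
      v <- c(v, paste(col, "defined at or after offspring"))
    }
  }
  sire_sex <- ped$sex[match(setdiff(ped$sire, 0), ped$id)]
  dam_sex <- ped$sex[match(setdiff(ped$dam, 0), ped$id)]
  if (any(sire_sex != "M", na.rm = TRUE)) v <- c(v, "female used as sire")
  if (any(dam_sex != "F", na.rm = TRUE)) v <- c(v, "male used as dam")
  half <- (ped$sire == 0) != (ped$dam == 0)
  if (any(half)) v <- c(v, "individual with exactly one known parent")
  if ("generation" %in% names(ped)) {
    base_bad <- ped$generation == 0 & (ped$sire != 0 | ped$dam != 0)
    if (any(base_bad)) v <- c(v, "generation-0 individual with parents")
  }
  v
}
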