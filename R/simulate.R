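# Synthetic genotype and sequence generators with planted truth.

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulation configuration
#'
#' Describes a two-type, partly clonal microsatellite dataset: `n_pops`
#' partially isolated groups at Balding-Nichols divergence `divergence_f`,
#' each holding `genets_per_pop` genets sampled as `colonies_per_pop`
#' colonies (ramets allocated at random, every genet sampled at least
#' once), typed at `n_loci` loci with `alleles_per_locus` ancestral
#' alleles. Per-ramet single-locus somatic mutations (stepwise, +/- one
#' repeat unit), per-call scoring errors (random in-locus allele), and
#' per-genotype missing calls are planted at the given rates. Defaults
#' mirror the study system this generator emulates: 10 + 7 genets among
#' 53 + 44 colonies, 11 cross-type loci with about 8 alleles each, and
#' weak but significant divergence (F = 0.08).
#'
#' @param n_pops number of populations/types (labelled `mt-L`, `mt-S`, ...)
#' @param divergence_f Balding-Nichols F in `[0, 1)`; 0 means one panmictic
#'   pool
#' @param n_loci number of loci
#' @param alleles_per_locus ancestral alleles per locus (>= 2)
#' @param unit_length_per_locus repeat unit length per locus (3 or 4,
#'   recycled)
#' @param genets_per_pop genets per population (recycled to `n_pops`)
#' @param colonies_per_pop sampled colonies per population (recycled);
#'   must be >= genets_per_pop
#' @param p_somatic per-ramet probability of one single-locus somatic
#'   mutation
#' @param p_error per-call probability of replacing a call with a random
#'   in-locus allele
#' @param p_missing per-genotype probability of a missing (0, 0) call
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_pops = 2L, divergence_f = 0.08, n_loci = 11L,
                       alleles_per_locus = 8L,
                       unit_length_per_locus = c(3L, 4L),
                       genets_per_pop = c(10L, 7L),
                       colonies_per_pop = c(53L, 44L),
                       p_somatic = 0.02, p_error = 0.005, p_missing = 0.01) {
  stopifnot(n_pops >= 1L, divergence_f >= 0, divergence_f < 1,
            n_loci >= 1L, alleles_per_locus >= 2L,
            all(unit_length_per_locus %in% c(3L, 4L)),
            p_somatic >= 0, p_somatic <= 1, p_error >= 0, p_error <= 1,
            p_missing >= 0, p_missing <= 1)
  genets_per_pop <- rep_len(as.integer(genets_per_pop), n_pops)
  colonies_per_pop <- rep_len(as.integer(colonies_per_pop), n_pops)
  stopifnot(all(genets_per_pop >= 1L),
            all(colonies_per_pop >= genets_per_pop))
  structure(list(n_pops = as.integer(n_pops), divergence_f = divergence_f,
                 n_loci = as.integer(n_loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 unit_length_per_locus =
                   rep_len(as.integer(unit_length_per_locus), n_loci),
                 genets_per_pop = genets_per_pop,
                 colonies_per_pop = colonies_per_pop,
                 p_somatic = p_somatic, p_error = p_error,
                 p_missing = p_missing),
            class = "sim_config")
}

#' Simulate a genotype dataset with planted truth
#'
#' Generates a [genotype_matrix()] under the model described in
#' [sim_config()]:
#' ancestral allele frequencies at each locus are drawn from a symmetric
#' Dirichlet(1); population frequencies follow the Balding-Nichols model,
#' Dirichlet centred on the ancestral vector with concentration
#' \eqn{(1 - F)/F} (at \eqn{F = 0} every population shares the ancestral
#' frequencies exactly); genet genotypes are drawn under within-population
#' Hardy-Weinberg; colonies copy their genet's genotype; somatic
#' mutations, scoring errors and missing calls are then planted at the
#' configured rates. Allele sizes are emitted in base pairs:
#' per-locus offset (drawn once, so ranges land in roughly 150-450 bp)
#' plus unit length times repeat count.
#'
#' @param config a [sim_config()]
#' @param seed optional RNG seed (identical config + seed reproduces the
#'   dataset exactly)
#' @return list with `matrix` (the `genotype_matrix`) and `truth`, a list
#'   holding `genet` (sample -> genet label), `pop` (sample -> type
#'   label), `freqs` (list: pop x locus true frequencies), `somatic`,
#'   `errors`, `missing` (data.frames of planted coordinates)
#' @export
simulate_dataset <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  P <- config$n_pops; L <- config$n_loci; A <- config$alleles_per_locus
  f <- config$divergence_f
  pops <- paste0("mt-", c("L", "S", LETTERS[seq_len(max(0, P - 2L))]))[seq_len(P)]

  # allele size maps: offset + unit * (repeat count 1..A)
  unit <- config$unit_length_per_locus
  offset <- sapply(seq_len(L), function(j)
    sample(seq(150L, 450L - unit[j] * A), 1L))
  sizes <- lapply(seq_len(L), function(j) offset[j] + unit[j] * seq_len(A))

  anc <- lapply(seq_len(L), function(j) rdirichlet1(rep(1, A)))
  freqs <- lapply(seq_len(P), function(p) {
    lapply(seq_len(L), function(j) {
      if (f == 0) anc[[j]] else rdirichlet1(anc[[j]] * (1 - f) / f)
    })
  })
  names(freqs) <- pops

  n_tot <- sum(config$colonies_per_pop)
  tab <- matrix(0, n_tot, 2L * L)
  genet_lab <- character(n_tot); pop_lab <- character(n_tot)
  sid <- sprintf("c%03d", seq_len(n_tot))
  rownames(tab) <- sid
  row <- 0L
  somatic <- list(); errors <- list(); missing <- list()
  for (p in seq_len(P)) {
    G <- config$genets_per_pop[p]; n <- config$colonies_per_pop[p]
    # genet genotypes: allele indices, HWE within population
    geno <- array(0L, c(G, L, 2L))
    for (j in seq_len(L)) {
      pr <- freqs[[p]][[j]]
      geno[, j, ] <- sample.int(A, 2L * G, replace = TRUE, prob = pr)
    }
    # allocate colonies to genets: each genet at least once, rest uniform
    alloc <- c(seq_len(G), sample.int(G, n - G, replace = TRUE))
    alloc <- sample(alloc)  # shuffle so ramets are interleaved
    for (i in seq_len(n)) {
      row <- row + 1L
      g <- alloc[i]
      genet_lab[row] <- paste0(pops[p], "_g", g)
      pop_lab[row] <- pops[p]
      idx <- geno[g, , , drop = FALSE]  # 1 x L x 2 allele indices
      calls <- matrix(0, L, 2L)
      for (j in seq_len(L)) calls[j, ] <- sizes[[j]][idx[1L, j, ]]
      # somatic mutation: one random locus, one allele, +/- 1 repeat unit
      if (stats::runif(1) < config$p_somatic) {
        j <- sample.int(L, 1L); c2 <- sample.int(2L, 1L)
        shift <- sample(c(-1L, 1L), 1L) * unit[j]
        calls[j, c2] <- calls[j, c2] + shift
        somatic[[length(somatic) + 1L]] <-
          data.frame(sample_id = sid[row], locus = j, shift_bp = shift)
      }
      # scoring errors: replace a call with a random in-locus allele
      err <- which(matrix(stats::runif(2L * L) < config$p_error, L, 2L),
                   arr.ind = TRUE)
      for (e in seq_len(nrow(err))) {
        j <- err[e, 1L]
        calls[j, err[e, 2L]] <- sizes[[j]][sample.int(A, 1L)]
        errors[[length(errors) + 1L]] <-
          data.frame(sample_id = sid[row], locus = j)
      }
      # missing genotypes
      mis <- which(stats::runif(L) < config$p_missing)
      calls[mis, ] <- 0
      for (j in mis)
        missing[[length(missing) + 1L]] <-
          data.frame(sample_id = sid[row], locus = j)
      tab[row, ] <- as.vector(t(calls))
    }
  }
  lids <- sprintf("L%02d", seq_len(L))
  loci <- data.frame(locus_id = lids, motif = NA_character_,
                     unit_length = unit, cross_type = TRUE,
                     accession = NA_character_)
  gm <- genotype_matrix(tab, loci, mito_type = pop_lab)
  bindrows <- function(x) if (length(x)) do.call(rbind, x) else
    data.frame(sample_id = character(0), locus = integer(0))
  truth <- list(genet = stats::setNames(genet_lab, sid),
                pop = stats::setNames(pop_lab, sid),
                freqs = freqs, allele_sizes = sizes,
                somatic = bindrows(somatic), errors = bindrows(errors),
                missing = bindrows(missing))
  list(matrix = gm, truth = truth)
}

#' Simulate sequences with planted tandem repeats
#'
#' Builds FASTA-ready sequences, each holding one planted perfect repeat
#' flanked by random sequence. Flanks are regenerated until they contain
#' no tandem run of 4 or more units of any 3- or 4-base motif, and the
#' bases adjoining the repeat are constrained not to extend its
#' periodicity, so discovery recovers exactly the planted repeat with its
#' planted phase.
#'
#' @param planted list (or data.frame) of `(motif, n_units)` pairs, one
#'   per sequence
#' @param flank_length flank length on each side (default 60)
#' @param seed optional RNG seed
#' @return list with `seqs` (named character vector) and `truth`
#'   (data.frame: seq_id, start, end, motif, unit_length, n_units)
#' @export
simulate_repeat_sequences <- function(planted, flank_length = 60L,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(planted))
    planted <- lapply(seq_len(nrow(planted)), function(i)
      list(motif = planted$motif[i], n_units = planted$n_units[i]))
  seqs <- character(0); truth <- list()
  for (i in seq_along(planted)) {
    motif <- toupper(planted[[i]]$motif)
    k <- as.integer(planted[[i]]$n_units)
    stopifnot(grepl("^[ACGT]+$", motif), k >= 1L)
    u <- nchar(motif)
    rep_seq <- strrep(motif, k)
    left <- clean_flank(flank_length)
    right <- clean_flank(flank_length)
    # do not let flank bases extend the periodic region on either side
    while (substr(left, flank_length, flank_length) ==
           substr(motif, u, u))
      left <- clean_flank(flank_length)
    while (substr(right, 1L, 1L) == substr(motif, 1L, 1L))
      right <- clean_flank(flank_length)
    id <- sprintf("seq%03d", i)
    seqs[id] <- paste0(left, rep_seq, right)
    truth[[i]] <- data.frame(seq_id = id, start = flank_length + 1L,
                             end = flank_length + u * k, motif = motif,
                             unit_length = u, n_units = k,
                             stringsAsFactors = FALSE)
  }
  list(seqs = seqs, truth = do.call(rbind, truth))
}

clean_flank <- function(len) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    hits <- find_tandem_repeats(s, min_units = 4L)
    if (nrow(hits) == 0L) return(s)
  }
}
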