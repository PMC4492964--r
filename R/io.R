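#' Read a multilocus genotype table
#'
#' Parses one of the three genotype dialects used by the field's standard
#' toolchain. The dialect is always stated explicitly; no format sniffing.
#'
#' * `genalex`: CSV with a counts line (`n_loci,n_samples,n_pops,sizes...`),
#'   a title line whose 4th field onward names the populations, a header
#'   line (`Sample,Pop,<locus>,,...`), then one row per sample with two
#'   allele columns per locus. Alleles are fragment sizes in bp, 0 missing.
#' * `structure`: whitespace-separated, one header line of locus names,
#'   then one row per individual: label, pop code, two integer columns per
#'   locus; missing is -9. Alleles are small integer codes; a sidecar
#'   dictionary (`<path>.alleles.tsv`, written by [write_genotype_table()])
#'   maps codes back to bp sizes and pop codes back to labels.
#' * `genepop`: title line, one locus name per line, `Pop` separators,
#'   sample lines `id , aaabbb ...` with 3-digit allele codes (the bp
#'   size, zero-padded), `000000` missing. Population labels round-trip
#'   through a `pops:` clause this package writes into the title line.
#'
#' Missing calls are normalized to `(0, 0)`; sample and locus order are
#' preserved from the file. Malformed input fails with the offending line
#' number.
#'
#' @param path file path
#' @param dialect one of `"genalex"`, `"structure"`, `"genepop"`
#' @return a [genotype_matrix()]
#' @seealso [write_genotype_table()]
#' @export
read_genotype_table <- function(path, dialect = c("genalex", "structure", "genepop")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         genalex = read_genalex(path),
         structure = read_structure(path),
         genepop = read_genepop(path))
}

#' Write a multilocus genotype table
#'
#' Inverse of [read_genotype_table()]: the emitted file re-reads to an
#' equal matrix. The `structure` dialect recodes alleles per locus to
#' consecutive integers and persists the code-to-bp dictionary next to the
#' file (`<path>.alleles.tsv`), with missing coded -9.
#'
#' @param x a [genotype_matrix()]
#' @param path output path
#' @param dialect one of `"genalex"`, `"structure"`, `"genepop"`
#' @return `path`, invisibly
#' @export
write_genotype_table <- function(x, path, dialect = c("genalex", "structure", "genepop")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "genotype_matrix"))
  if (n_loci(x) < 1L) stop("matrix has no loci")
  if (n_samples(x) < 1L) stop("matrix has no samples")
  switch(dialect,
         genalex = write_genalex(x, path),
         structure = write_structure(x, path),
         genepop = write_genepop(x, path))
  invisible(path)
}

pop_labels <- function(x) {
  if (!is.null(x$mito_type) && !anyNA(x$mito_type)) x$mito_type else x$population
}

parse_fail <- function(path, line, msg) {
  stop("parse error in '", path, "' at line ", line, ": ", msg, call. = FALSE)
}

check_bp_range <- function(tab, path) {
  nz <- tab[tab != 0]
  if (length(nz) && (any(nz < 50) || any(nz > 600)))
    stop("allele size out of the plausible fragment range [50, 600] bp in '",
         path, "'")
}

## ---- GenAlEx ----

write_genalex <- function(x, path) {
  L <- n_loci(x); n <- n_samples(x)
  pop <- pop_labels(x)
  pops <- unique(pop)
  ord <- order(match(pop, pops))
  sizes <- as.integer(table(factor(pop, levels = pops)))
  lines <- c(
    paste(c(L, n, length(pops), sizes), collapse = ","),
    paste(c("msatclone export", "", "", pops), collapse = ","),
    paste(c("Sample", "Pop",
            as.vector(rbind(locus_ids(x), ""))), collapse = ","))
  tab <- x$tab[ord, , drop = FALSE]
  rows <- vapply(seq_len(n), function(i)
    paste(c(rownames(tab)[i], pop[ord][i],
            format(tab[i, ], trim = TRUE, scientific = FALSE)),
          collapse = ","), character(1))
  writeLines(c(lines, rows), path)
}

read_genalex <- function(path) {
  raw <- readLines(path)
  if (length(raw) < 4L) parse_fail(path, length(raw), "file too short")
  hdr <- strsplit(raw[1L], ",", fixed = TRUE)[[1L]]
  cnt <- suppressWarnings(as.integer(hdr))
  if (length(cnt) < 3L || anyNA(cnt[1:3]))
    parse_fail(path, 1L, "expected 'n_loci,n_samples,n_pops,...' counts")
  L <- cnt[1L]; n <- cnt[2L]
  head3 <- strsplit(raw[3L], ",", fixed = TRUE)[[1L]]
  # strsplit drops a trailing empty field, hence 2L*L + 1 not 2L*L + 2
  if (length(head3) < 2L * L + 1L)
    parse_fail(path, 3L, "header names fewer loci than the counts line declares")
  lids <- head3[seq(3L, by = 2L, length.out = L)]
  if (any(lids == "")) parse_fail(path, 3L, "empty locus name")
  data <- raw[-(1:3)]
  data <- data[!grepl("^[,\\s]*$", data)]
  if (length(data) != n)
    parse_fail(path, 3L + length(data) + 1L,
               sprintf("expected %d sample rows, found %d", n, length(data)))
  tab <- matrix(0, n, 2L * L)
  ids <- character(n); pop <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(data[i], ",", fixed = TRUE)[[1L]]
    if (length(f) != 2L + 2L * L)
      parse_fail(path, 3L + i, sprintf(
        "expected %d fields (sample, pop, 2 alleles x %d loci), found %d",
        2L + 2L * L, L, length(f)))
    ids[i] <- f[1L]; pop[i] <- f[2L]
    v <- suppressWarnings(as.numeric(f[-(1:2)]))
    if (anyNA(v)) parse_fail(path, 3L + i, "non-numeric allele call")
    tab[i, ] <- v
  }
  rownames(tab) <- ids
  check_bp_range(tab, path)
  mito <- if (all(grepl("^mt-", pop))) pop else NULL
  genotype_matrix(tab, lids, mito_type = mito, population = pop)
}

## ---- STRUCTURE ----

write_structure <- function(x, path) {
  L <- n_loci(x); n <- n_samples(x)
  pop <- pop_labels(x)
  pops <- unique(pop)
  popcode <- match(pop, pops)
  dict <- vector("list", L)
  coded <- matrix(-9L, n, 2L * L)
  for (j in seq_len(L)) {
    g <- genotypes_at(x, j)
    sizes <- sort(unique(as.vector(g[g != 0])))
    dict[[j]] <- data.frame(record = "allele", locus_id = locus_ids(x)[j],
                            code = seq_along(sizes), value = sizes)
    for (c2 in 1:2) {
      v <- g[, c2]
      coded[, 2L * j - 2L + c2] <- ifelse(v == 0, -9L, match(v, sizes))
    }
  }
  lines <- c(paste(locus_ids(x), collapse = " "),
             vapply(seq_len(n), function(i)
               paste(c(rownames(x$tab)[i], popcode[i], coded[i, ]),
                     collapse = " "), character(1)))
  writeLines(lines, path)
  dict <- do.call(rbind, dict)
  dict <- rbind(dict,
                data.frame(record = "pop", locus_id = "",
                           code = seq_along(pops), value = pops))
  utils::write.table(dict, paste0(path, ".alleles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

read_structure <- function(path) {
  raw <- readLines(path)
  raw <- raw[!grepl("^\\s*$", raw)]
  if (length(raw) < 2L) parse_fail(path, length(raw), "file too short")
  lids <- strsplit(trimws(raw[1L]), "\\s+")[[1L]]
  L <- length(lids)
  n <- length(raw) - 1L
  tab <- matrix(0, n, 2L * L)
  ids <- character(n); popcode <- integer(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(raw[i + 1L]), "\\s+")[[1L]]
    if (length(f) != 2L + 2L * L)
      parse_fail(path, i + 1L, sprintf(
        "expected %d fields, found %d (one-row-per-individual layout)",
        2L + 2L * L, length(f)))
    ids[i] <- f[1L]
    popcode[i] <- suppressWarnings(as.integer(f[2L]))
    v <- suppressWarnings(as.integer(f[-(1:2)]))
    if (anyNA(v)) parse_fail(path, i + 1L, "non-integer allele code")
    v[v == -9L] <- 0L
    tab[i, ] <- v
  }
  # half-missing codes are a format violation, not a data point
  a1 <- tab[, seq(1L, 2L * L, 2L)]; a2 <- tab[, seq(2L, 2L * L, 2L)]
  if (any(xor(a1 == 0, a2 == 0)))
    parse_fail(path, which(rowSums(xor(a1 == 0, a2 == 0)) > 0)[1L] + 1L,
               "half-missing genotype (-9 paired with a call)")
  rownames(tab) <- ids
  dictfile <- paste0(path, ".alleles.tsv")
  pop <- as.character(popcode)
  if (file.exists(dictfile)) {
    dict <- utils::read.table(dictfile, sep = "\t", header = TRUE,
                              colClasses = c("character", "character",
                                             "integer", "character"))
    for (j in seq_len(L)) {
      d <- dict[dict$record == "allele" & dict$locus_id == lids[j], ]
      for (c2 in 1:2) {
        col <- 2L * j - 2L + c2
        v <- tab[, col]
        dec <- as.numeric(d$value)[match(v, d$code)]
        tab[, col] <- ifelse(v == 0, 0, dec)
      }
    }
    if (anyNA(tab)) parse_fail(path, 2L, "allele code absent from dictionary")
    dp <- dict[dict$record == "pop", ]
    pop <- dp$value[match(popcode, dp$code)]
  }
  mito <- if (all(grepl("^mt-", pop))) pop else NULL
  genotype_matrix(tab, lids, mito_type = mito, population = pop)
}

## ---- Genepop ----

write_genepop <- function(x, path) {
  if (any(x$tab > 999))
    stop("genepop 3-digit codes cannot hold allele sizes > 999 bp")
  pop <- pop_labels(x)
  pops <- unique(pop)
  lines <- c(paste0("msatclone export; pops: ", paste(pops, collapse = ",")),
             locus_ids(x))
  for (p in pops) {
    lines <- c(lines, "Pop")
    for (i in which(pop == p)) {
      codes <- sprintf("%03d", as.integer(x$tab[i, ]))
      g <- paste(codes[seq(1, length(codes), 2)],
                 codes[seq(2, length(codes), 2)], sep = "")
      lines <- c(lines, paste0(rownames(x$tab)[i], " , ", paste(g, collapse = " ")))
    }
  }
  writeLines(lines, path)
}

read_genepop <- function(path) {
  raw <- readLines(path)
  if (length(raw) < 3L) parse_fail(path, length(raw), "file too short")
  title <- raw[1L]
  pops_decl <- NULL
  if (grepl("pops:", title, fixed = TRUE))
    pops_decl <- strsplit(trimws(sub(".*pops:", "", title)), ",")[[1L]]
  ispop <- toupper(trimws(raw)) == "POP"
  first_pop <- which(ispop)[1L]
  if (is.na(first_pop)) parse_fail(path, length(raw), "no 'Pop' separator")
  lids <- trimws(raw[2:(first_pop - 1L)])
  lids <- unlist(strsplit(lids, ","))
  lids <- trimws(lids[lids != ""])
  L <- length(lids)
  ids <- character(0); pop <- integer(0); rows <- list()
  popn <- 0L
  for (ln in seq(first_pop, length(raw))) {
    line <- trimws(raw[ln])
    if (line == "") next
    if (toupper(line) == "POP") { popn <- popn + 1L; next }
    parts <- strsplit(line, ",", fixed = TRUE)[[1L]]
    if (length(parts) < 2L)
      parse_fail(path, ln, "sample line must be 'id , genotypes'")
    id <- trimws(parts[1L])
    g <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "\\s+")[[1L]]
    if (length(g) != L)
      parse_fail(path, ln, sprintf("expected %d genotype fields, found %d",
                                   L, length(g)))
    if (!all(grepl("^[0-9]{6}$", g)))
      parse_fail(path, ln, "genotypes must be 6-digit (two 3-digit alleles)")
    a1 <- as.numeric(substr(g, 1L, 3L)); a2 <- as.numeric(substr(g, 4L, 6L))
    if (any(xor(a1 == 0, a2 == 0)))
      parse_fail(path, ln, "half-missing genotype (000 paired with a call)")
    ids <- c(ids, id); pop <- c(pop, popn)
    rows[[length(rows) + 1L]] <- as.vector(rbind(a1, a2))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- ids
  check_bp_range(tab, path)
  labels <- if (!is.null(pops_decl) && length(pops_decl) == popn)
    pops_decl[pop] else paste0("Pop_", pop)
  mito <- if (all(grepl("^mt-", labels))) labels else NULL
  genotype_matrix(tab, lids, mito_type = mito, population = labels)
}
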