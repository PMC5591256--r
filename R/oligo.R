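# Mixmer oligonucleotide model: parsing of the LNA/DNA/TINA notation used
# for triplex-forming oligonucleotides (TFOs), complement rules and binding
# site location.

OLIGO_ATTRS <- c("oligo_name", "label5", "label3")

new_oligo <- function(monomers, name = NA_character_,
                      label5 = NA_character_, label3 = NA_character_) {
  out <- tibble::new_tibble(monomers, class = "oligo",
                            oligo_name = name, label5 = label5, label3 = label3)
  out
}

#' @exportS3Method pillar::tbl_sum
tbl_sum.oligo <- function(x, ...) {
  c("Oligo" = sprintf("%s: %d nt (%d LNA, %d TINA)",
                      attr(x, "oligo_name") %||% "<unnamed>",
                      sum(!is.na(x$base)), sum(x$chemistry == "LNA"),
                      sum(x$chemistry == "TINA")))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Parse mixmer oligonucleotide notation
#'
#' Interprets the compact notation used for LNA/DNA mixmer oligonucleotides:
#' lowercase letters are DNA nucleotides, uppercase letters are LNA
#' nucleotides, `P` (optionally bold, `**P**`) is a base-free TINA
#' intercalating monomer, `Cy3`/`Cy5` tokens are terminal fluorophore
#' labels, and `-` separates segments (for example the TFO arm, linker and
#' Watson-Crick arm of a bisLNA clamp). `5'-`/`-3'` decorations (with prime
#' characters or plain apostrophes) are accepted and a `3'-...-5'` string is
#' reversed to the internal 5' to 3' orientation.
#'
#' @param notation A notation string.
#' @param name Optional name stored on the result.
#' @param tina_strict If `TRUE`, TINA must be written as `**P**`; a bare `P`
#'   is then a parse error. Default `FALSE` accepts both.
#' @return An `oligo`: a tibble with one row per monomer and columns
#'   `pos` (monomer index from the 5' end), `nt_pos` (nucleotide index, `NA`
#'   for TINA), `base` (`A`/`C`/`G`/`T` or `NA`), `chemistry`
#'   (`DNA`/`LNA`/`TINA`), `protonated` and `segment`. Attributes carry the
#'   name and any 5'/3' labels.
#' @examples
#' on2 <- parse_mixmer("5'-CcTtTtCtTtTtTcT-3'", name = "ON2")
#' count_lna(on2)
#' @export
parse_mixmer <- function(notation, name = NA_character_, tina_strict = FALSE) {
  if (!is.character(notation) || length(notation) != 1 || is.na(notation)) {
    abort("`notation` must be a single string", class = "lnahelix_parse_error")
  }
  s <- notation
  # normalize prime characters and whitespace
  s <- gsub("′|´|’", "'", s)
  s <- gsub("\\s", "", s)

  reversed <- FALSE
  if (grepl("^3'-", s) && grepl("-5'$", s)) reversed <- TRUE
  s <- sub("^[53]'-", "", s)
  s <- sub("-[53]'$", "", s)

  # bold TINA token -> plain P; in strict mode a bare P is rejected first
  if (tina_strict) {
    s_nobold <- gsub("\\*\\*P\\*\\*", "", s)
    if (grepl("P", s_nobold, fixed = TRUE)) {
      abort("bare 'P': TINA must be written **P** in strict mode",
            class = "lnahelix_parse_error")
    }
  }
  s <- gsub("\\*\\*P\\*\\*", "P", s)
  if (grepl("\\*", s)) {
    abort("stray '*' in notation (TINA is '**P**')", class = "lnahelix_parse_error")
  }

  # terminal labels
  label5 <- NA_character_; label3 <- NA_character_
  m <- regmatches(s, regexec("^(Cy[35])-", s))[[1]]
  if (length(m)) { if (reversed) label3 <- m[2] else label5 <- m[2]; s <- sub("^Cy[35]-", "", s) }
  m <- regmatches(s, regexec("-(Cy[35])$", s))[[1]]
  if (length(m)) { if (reversed) label5 <- m[2] else label3 <- m[2]; s <- sub("-Cy[35]$", "", s) }

  segments <- strsplit(s, "-", fixed = TRUE)[[1]]
  if (any(nchar(segments) == 0)) {
    abort("empty segment (consecutive '-') in notation", class = "lnahelix_parse_error")
  }
  if (reversed) segments <- rev(segments)

  rows <- list()
  pos <- 0L
  for (si in seq_along(segments)) {
    chars <- strsplit(segments[si], "")[[1]]
    if (reversed) chars <- rev(chars)
    for (ch in chars) {
      pos <- pos + 1L
      if (ch == "P") {
        rows[[pos]] <- list(base = NA_character_, chemistry = "TINA", segment = si)
      } else if (ch %in% c("a", "c", "g", "t")) {
        rows[[pos]] <- list(base = toupper(ch), chemistry = "DNA", segment = si)
      } else if (ch %in% c("A", "C", "G", "T")) {
        rows[[pos]] <- list(base = ch, chemistry = "LNA", segment = si)
      } else {
        abort(sprintf("unknown character '%s' at monomer position %d", ch, pos),
              class = "lnahelix_parse_error")
      }
    }
  }
  monomers <- tibble(
    pos = seq_along(rows),
    base = vapply(rows, function(r) r$base, character(1)),
    chemistry = vapply(rows, function(r) r$chemistry, character(1)),
    segment = vapply(rows, function(r) r$segment, integer(1))
  )
  monomers$nt_pos <- NA_integer_
  has_base <- !is.na(monomers$base)
  monomers$nt_pos[has_base] <- seq_len(sum(has_base))
  monomers$protonated <- FALSE
  monomers <- monomers[, c("pos", "nt_pos", "base", "chemistry", "protonated", "segment")]
  new_oligo(monomers, name = name, label5 = label5, label3 = label3)
}

#' Serialize an oligo back to mixmer notation
#'
#' Inverse of [parse_mixmer()]: lowercase for DNA, uppercase for LNA,
#' `**P**` for TINA, `-` between segments and `Cy3-`/`Cy5-` labels, with
#' `5'-`/`-3'` decorations.
#'
#' @param oligo An `oligo`.
#' @return A notation string in 5' to 3' orientation.
#' @export
format_mixmer <- function(oligo) {
  stopifnot(inherits(oligo, "oligo"))
  char1 <- function(base, chem) {
    if (chem == "TINA") return("**P**")
    if (chem == "LNA") base else tolower(base)
  }
  segs <- split(oligo, oligo$segment)
  body <- vapply(segs, function(seg) {
    paste0(mapply(char1, seg$base, seg$chemistry), collapse = "")
  }, character(1))
  out <- paste0(body, collapse = "-")
  l5 <- attr(oligo, "label5"); l3 <- attr(oligo, "label3")
  if (!is.na(l5 %||% NA)) out <- paste0(l5, "-", out)
  if (!is.na(l3 %||% NA)) out <- paste0(out, "-", l3)
  paste0("5'-", out, "-3'")
}

#' Count LNA monomers in an oligo
#'
#' @param oligo An `oligo` from [parse_mixmer()].
#' @return Integer count of LNA nucleotides.
#' @export
count_lna <- function(oligo) {
  stopifnot(inherits(oligo, "oligo"))
  sum(oligo$chemistry == "LNA")
}

#' Nucleotide length of an oligo
#'
#' The number of base-carrying monomers; TINA intercalators are excluded.
#'
#' @param oligo An `oligo`.
#' @return Integer nucleotide count.
#' @export
nt_length <- function(oligo) {
  stopifnot(inherits(oligo, "oligo"))
  sum(!is.na(oligo$base))
}

oligo_bases <- function(oligo) {
  b <- oligo$base[!is.na(oligo$base)]
  paste0(b, collapse = "")
}

check_bases <- function(s, allowed = c("A", "C", "G", "T"), what = "sequence") {
  chars <- strsplit(toupper(s), "")[[1]]
  bad <- which(!chars %in% allowed)
  if (length(bad)) {
    abort(sprintf("%s contains invalid base '%s' at position %d",
                  what, chars[bad[1]], bad[1]),
          class = "lnahelix_parse_error")
  }
  chars
}

#' Watson-Crick complement
#'
#' Antiparallel complement of a base sequence (A to T, G to C), returned in
#' 5' to 3' orientation, i.e. the reverse complement.
#'
#' @param s A base string (case-insensitive, `A`/`C`/`G`/`T`).
#' @return The complementary strand, 5' to 3', in lowercase.
#' @examples
#' wc_complement("ggggaaaagaaaaaagatc")
#' @export
wc_complement <- function(s) {
  chars <- check_bases(s, what = "strand")
  comp <- c(A = "t", T = "a", G = "c", C = "g")[chars]
  paste0(rev(comp), collapse = "")
}

#' Parallel Hoogsteen complement of a purine tract
#'
#' Position-wise third-strand complement for a pyrimidine-motif triplex:
#' the TFO runs parallel to the purine strand, pairing A with T and G with
#' protonated C (C+). No reversal is applied.
#'
#' @param s A purine-only base string (`A`/`G`).
#' @return A tibble with columns `pos`, `purine`, `base` (TFO base, `T` or
#'   `C`) and `protonated` (`TRUE` for every C). The plain TFO sequence is
#'   in attribute `"sequence"` and via `as.character()` on the result's
#'   `base` column.
#' @examples
#' hoogsteen_parallel_complement("ggaaaagaaaaaaga")
#' @export
hoogsteen_parallel_complement <- function(s) {
  chars <- check_bases(s, what = "purine tract")
  pyr <- which(!chars %in% c("A", "G"))
  if (length(pyr)) {
    abort(sprintf("pyrimidine '%s' at position %d: the Hoogsteen target must be a purine tract",
                  chars[pyr[1]], pyr[1]),
          class = "lnahelix_parse_error")
  }
  base <- ifelse(chars == "A", "T", "C")
  out <- tibble(pos = seq_along(chars), purine = chars, base = base,
                protonated = base == "C")
  attr(out, "sequence") <- tolower(paste0(base, collapse = ""))
  out
}

#' Construct a duplex target
#'
#' A duplex target is the double-stranded DNA that a TFO binds. The purine
#' strand is the strand carrying the polypurine tract; the pyrimidine strand
#' must be its full-length antiparallel Watson-Crick complement (chemistry
#' may differ: an LNA-containing strand makes the target a hetero-duplex).
#'
#' @param purine_strand,pyrimidine_strand `oligo` objects or notation
#'   strings (both 5' to 3'). If `pyrimidine_strand` is `NULL` it is derived
#'   as the all-DNA Watson-Crick complement.
#' @param site Optional 1-based closed interval `c(start, end)` on the
#'   purine strand marking the TFO binding site.
#' @param name Optional name.
#' @return A `duplex_target` list with elements `purine`, `pyrimidine`,
#'   `site`, `name` and `hetero`.
#' @export
duplex_target <- function(purine_strand, pyrimidine_strand = NULL,
                          site = NULL, name = NA_character_) {
  pur <- if (inherits(purine_strand, "oligo")) purine_strand else parse_mixmer(purine_strand)
  if (is.null(pyrimidine_strand)) {
    pyr <- parse_mixmer(wc_complement(oligo_bases(pur)))
  } else {
    pyr <- if (inherits(pyrimidine_strand, "oligo")) pyrimidine_strand else parse_mixmer(pyrimidine_strand)
  }
  bp <- oligo_bases(pur)
  bq <- oligo_bases(pyr)
  if (nchar(bp) != nchar(bq)) {
    abort("strands differ in nucleotide length", class = "lnahelix_duplex_error")
  }
  comp <- toupper(wc_complement(bp))
  if (comp != bq) {
    mism <- which(strsplit(comp, "")[[1]] != strsplit(bq, "")[[1]])[1]
    abort(sprintf("strands are not Watson-Crick complementary (first mismatch at pyrimidine-strand position %d)", mism),
          class = "lnahelix_duplex_error")
  }
  if (!is.null(site)) {
    stopifnot(length(site) == 2, site[1] >= 1, site[2] <= nt_length(pur), site[1] <= site[2])
  }
  structure(
    list(purine = pur, pyrimidine = pyr, site = site, name = name,
         hetero = any(pur$chemistry == "LNA") || any(pyr$chemistry == "LNA")),
    class = "duplex_target"
  )
}

#' @export
print.duplex_target <- function(x, ...) {
  cat(sprintf("<duplex_target> %s: %d bp (%s)\n",
              x$name %||% "<unnamed>", nt_length(x$purine),
              if (x$hetero) "hetero-duplex" else "homo-duplex"))
  cat("  purine    5'-", oligo_bases(x$purine), "-3'\n", sep = "")
  cat("  pyrimidine 5'-", oligo_bases(x$pyrimidine), "-3'\n", sep = "")
  if (!is.null(x$site)) cat(sprintf("  binding site: [%d, %d]\n", x$site[1], x$site[2]))
  invisible(x)
}

#' Locate the TFO binding site on a duplex target
#'
#' Finds the unique window on the purine strand whose parallel Hoogsteen
#' complement equals the TFO base sequence exactly (no mismatches).
#'
#' @param duplex A `duplex_target`.
#' @param tfo An `oligo` or notation string. Its base letters must be
#'   pyrimidines (`C`/`T`).
#' @return Integer vector `c(start, end)`, a 1-based closed interval on the
#'   purine strand, or `NULL` when the site is absent.
#' @export
find_tfo_binding_site <- function(duplex, tfo) {
  stopifnot(inherits(duplex, "duplex_target"))
  tf <- if (inherits(tfo, "oligo")) tfo else parse_mixmer(tfo)
  tseq <- oligo_bases(tf)
  tchars <- check_bases(tseq, what = "TFO")
  pur <- which(!tchars %in% c("C", "T"))
  if (length(pur)) {
    abort(sprintf("TFO base '%s' at position %d is a purine: pyrimidine-motif TFOs contain only C and T",
                  tchars[pur[1]], pur[1]),
          class = "lnahelix_parse_error")
  }
  pchars <- strsplit(oligo_bases(duplex$purine), "")[[1]]
  m <- length(tchars); n <- length(pchars)
  if (m > n) return(NULL)
  hits <- list()
  for (s in seq_len(n - m + 1)) {
    win <- pchars[s:(s + m - 1)]
    if (any(!win %in% c("A", "G"))) next
    hg <- ifelse(win == "A", "T", "C")
    if (all(hg == tchars)) hits[[length(hits) + 1]] <- c(s, s + m - 1L)
  }
  if (length(hits) == 0) return(NULL)
  if (length(hits) > 1) {
    ivs <- paste(vapply(hits, function(h) sprintf("[%d,%d]", h[1], h[2]), character(1)), collapse = ", ")
    abort(sprintf("ambiguous target: TFO matches %d sites: %s", length(hits), ivs),
          class = "lnahelix_ambiguous_site_error")
  }
  as.integer(hits[[1]])
}

#' dsDNA : TFO hybridization ratio
#'
#' Ratio of oligonucleotide to duplex-target concentration. The ratio is
#' rounded to the nearest integer when within 1 percent of it, matching how
#' such ratios are conventionally reported (e.g. 1:12, 1:400).
#'
#' @param target_concentration,on_concentration Molar concentrations (same
#'   units), both positive.
#' @return Dimensionless ratio.
#' @examples
#' hybridization_ratio(5e-9, 2e-6) # 400
#' @export
hybridization_ratio <- function(target_concentration, on_concentration) {
  if (any(target_concentration <= 0) || any(on_concentration <= 0)) {
    abort("concentrations must be positive", class = "lnahelix_value_error")
  }
  r <- on_concentration / target_concentration
  rr <- round(r)
  ifelse(rr > 0 & abs(r - rr) / r <= 0.01, rr, r)
}

# ---- fixtures ---------------------------------------------------------------

#' Shipped oligonucleotide fixtures
#'
#' The studied mixmer oligonucleotides (TFOs, the Watson-Crick invader WC29
#' and the bisLNA clamp) with their printed lengths and notation, shipped as
#' a plain-text table.
#'
#' @return A tibble with columns `name`, `length` and `notation`.
#' @export
paper_oligos <- function() {
  path <- system.file("extdata", "oligos.tsv", package = "lnahelix", mustWork = TRUE)
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Shipped duplex target fixtures
#'
#' The duplex target sequences (c-MYC and FXN derived), with both strands in
#' printed orientation and the TFO binding site interval on the purine
#' strand.
#'
#' @return A tibble with columns `name`, `length`, `purine_notation`,
#'   `pyrimidine_notation`, `site_start`, `site_end`.
#' @export
paper_targets <- function() {
  path <- system.file("extdata", "targets.tsv", package = "lnahelix", mustWork = TRUE)
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Look up a shipped oligo by name
#'
#' @param name Fixture name, e.g. `"ON2"` or `"bisLNA49"`.
#' @return An `oligo`.
#' @export
get_oligo <- function(name) {
  tab <- paper_oligos()
  i <- match(name, tab$name)
  if (is.na(i)) {
    abort(sprintf("unknown oligo '%s'; see paper_oligos()", name), class = "lnahelix_lookup_error")
  }
  parse_mixmer(tab$notation[i], name = name)
}

#' Look up a shipped duplex target by name
#'
#' @param name Fixture name, e.g. `"c-MYC_DS19"`.
#' @return A `duplex_target` with the binding site set.
#' @export
get_target <- function(name) {
  tab <- paper_targets()
  i <- match(name, tab$name)
  if (is.na(i)) {
    abort(sprintf("unknown target '%s'; see paper_targets()", name), class = "lnahelix_lookup_error")
  }
  duplex_target(parse_mixmer(tab$purine_notation[i]),
                parse_mixmer(tab$pyrimidine_notation[i]),
                site = c(tab$site_start[i], tab$site_end[i]),
                name = name)
}

# ---- FASTA ------------------------------------------------------------------

#' Write oligos to FASTA with a chemistry sidecar
#'
#' FASTA stores only base letters, so per-position chemistry is written to a
#' sidecar TSV (`<path>.chem.tsv`) with columns `name`, `nt_pos`,
#' `chemistry`.
#'
#' @param oligos A named list of `oligo` objects.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_oligo_fasta <- function(oligos, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required for FASTA export")
  }
  seqs <- vapply(oligos, oligo_bases, character(1))
  xs <- Biostrings::DNAStringSet(seqs)
  names(xs) <- names(oligos) %||% paste0("oligo", seq_along(oligos))
  Biostrings::writeXStringSet(xs, path)
  chem <- purrr::imap_dfr(oligos, function(o, nm) {
    keep <- !is.na(o$base)
    tibble(name = nm, nt_pos = o$nt_pos[keep], chemistry = o$chemistry[keep])
  })
  write.table(chem, paste0(path, ".chem.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read oligos from FASTA (with optional chemistry sidecar)
#'
#' @param path FASTA path; if `<path>.chem.tsv` exists, per-position
#'   chemistry is restored, otherwise all positions are DNA.
#' @return A named list of `oligo` objects.
#' @export
read_oligo_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required for FASTA import")
  }
  xs <- Biostrings::readDNAStringSet(path)
  chem_path <- paste0(path, ".chem.tsv")
  chem <- if (file.exists(chem_path)) read.delim(chem_path, sep = "\t", stringsAsFactors = FALSE) else NULL
  out <- lapply(seq_along(xs), function(i) {
    nm <- names(xs)[i]
    bases <- strsplit(tolower(as.character(xs[[i]])), "")[[1]]
    if (!is.null(chem)) {
      ch <- chem[chem$name == nm, ]
      lna <- ch$nt_pos[ch$chemistry == "LNA"]
      bases[lna] <- toupper(bases[lna])
    }
    parse_mixmer(paste0(bases, collapse = ""), name = nm)
  })
  names(out) <- names(xs)
  out
}
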