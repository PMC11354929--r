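# GenBank flat-file reader/writer. No installed R package parses GenBank
# flat files, so the parser lives here; it covers the subset the pipeline
# needs (LOCUS topology, feature table with join()/complement() locations,
# ORIGIN sequence) and read_genbank(write_genbank(g)) is the identity on
# normalized genomes.

FEATURE_KEY_FOR_CLASS <- c(PCG = "CDS", ORF = "CDS", tRNA = "tRNA",
                           rRNA = "rRNA", tmRNA = "tmRNA", intron = "intron")

#' Read a GenBank flat file
#'
#' Parses one record: topology from the LOCUS line, organelle and taxon
#' metadata from the \code{source} feature, gene features from
#' \code{CDS}/\code{tRNA}/\code{rRNA}/\code{tmRNA}/\code{intron} keys
#' (standalone \code{gene} keys that duplicate a typed feature of the same
#' name are ignored), and sequence from ORIGIN. \code{join()} and
#' origin-wrapping locations are resolved into normalized interval lists;
#' CDS features are classed \code{ORF} when the gene name starts with
#' \code{"orf"}, \code{PCG} otherwise.
#'
#' @param path Path to a GenBank flat file.
#' @return An \code{\link{annotated_genome}}.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank record: no LOCUS line in ", path)
  topology <- if (grepl("circular", locus[1], ignore.case = TRUE))
    "circular" else "linear"
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "[[:space:]]+")[[1]][1]
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc)) {
    a <- strsplit(trimws(sub("^ACCESSION", "", acc[1])), "[[:space:]]+")[[1]][1]
    if (!is.na(a) && nzchar(a)) id <- a
  }

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank record has no ORIGIN sequence: ", path)
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori[1]][1] else length(lines) + 1L
  seq_lines <- lines[(ori[1] + 1L):(endrec - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("GenBank record has empty sequence: ", path)

  fstart <- grep("^FEATURES", lines)
  entries <- list()
  if (length(fstart)) {
    tbl <- lines[(fstart[1] + 1L):(ori[1] - 1L)]
    cur <- NULL
    for (ln in tbl) {
      if (grepl("^ {5}\\S", ln)) {               # new feature entry
        if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
        key <- sub("^ {5}(\\S+).*$", "\\1", ln)
        loc <- trimws(substring(ln, 22L))
        cur <- list(key = key, loc = loc, quals = character())
      } else if (grepl("^ {21}/", ln)) {         # qualifier
        cur$quals <- c(cur$quals, trimws(ln))
      } else if (!is.null(cur) && grepl("^ {21}", ln)) {
        if (length(cur$quals)) {                 # qualifier continuation
          cur$quals[length(cur$quals)] <-
            paste0(cur$quals[length(cur$quals)], " ", trimws(ln))
        } else {                                 # location continuation
          cur$loc <- paste0(cur$loc, trimws(ln))
        }
      }
    }
    if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
  }

  organelle <- "mt"; taxon <- NULL
  features <- list()
  for (e in entries) {
    if (e$key == "source") {
      org <- gb_qualifier(e$quals, "organelle")
      if (!is.na(org))
        organelle <- if (grepl("mitochond", org)) "mt" else "cp"
      species <- gb_qualifier(e$quals, "organism")
      note <- gb_qualifier(e$quals, "note")
      if (!is.na(species)) {
        tx <- list(order = "", family = "", genus = "", subgenus = "",
                   section = "")
        if (!is.na(note) && grepl("taxonomy:", note)) {
          for (kv in strsplit(sub(".*taxonomy:", "", note), ";")[[1]]) {
            p <- strsplit(trimws(kv), "=", fixed = TRUE)[[1]]
            if (length(p) == 2L && p[1] %in% names(tx)) tx[[p[1]]] <- p[2]
          }
        }
        taxon <- taxon_label(species, genus = tx$genus, family = tx$family,
                             order = tx$order, subgenus = tx$subgenus,
                             section = tx$section)
      }
      next
    }
    if (!e$key %in% c("CDS", "tRNA", "rRNA", "tmRNA", "intron", "gene")) next
    loc <- parse_gb_location(e$loc, feature = e$key)
    name <- gb_qualifier(e$quals, "gene")
    if (is.na(name)) name <- gb_qualifier(e$quals, "product")
    if (is.na(name)) name <- gb_qualifier(e$quals, "label")
    if (is.na(name)) name <- paste0(tolower(e$key), "_", length(features) + 1L)
    gene_class <- switch(e$key,
      CDS = if (grepl("^orf", name, ignore.case = TRUE)) "ORF" else "PCG",
      tRNA = "tRNA", rRNA = "rRNA", tmRNA = "tmRNA", intron = "intron",
      gene = "PCG")
    cs <- gb_qualifier(e$quals, "codon_start")
    tt <- gb_qualifier(e$quals, "transl_table")
    features[[length(features) + 1L]] <- list(
      key = e$key,
      feature = gene_feature(name, gene_class, loc$strand, loc$intervals,
                             codon_start = if (is.na(cs)) 1L else as.integer(cs),
                             transl_table = if (is.na(tt)) 1L else as.integer(tt)))
  }
  # drop bare `gene` entries shadowed by a typed feature of the same name
  typed <- vapply(Filter(function(x) x$key != "gene", features),
                  function(x) x$feature$name, "")
  keep <- Filter(function(x) x$key != "gene" || !(x$feature$name %in% typed),
                 features)
  annotated_genome(id, sequence, lapply(keep, `[[`, "feature"),
                   topology = topology, organelle = organelle, taxon = taxon)
}

gb_qualifier <- function(quals, name) {
  pat <- paste0("^/", name, "=")
  hit <- grep(pat, quals, value = TRUE)
  if (!length(hit)) {
    if (any(quals == paste0("/", name))) return("")
    return(NA_character_)
  }
  gsub("^\"|\"$", "", sub(pat, "", hit[1]))
}

# Location grammar subset: [complement(] [join(|order(] a..b, c, ... [)] [)]
parse_gb_location <- function(loc, feature = "?") {
  loc0 <- loc
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  iv <- lapply(parts, function(p) {
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^[0-9]+$", p)) {
      rep(as.integer(p), 2L)
    } else {
      stop("malformed location '", loc0, "' in feature ", feature)
    }
  })
  list(strand = strand, intervals = do.call(rbind, iv))
}

#' Write an annotated genome as a GenBank flat file
#'
#' Emits a parseable record that \code{\link{read_genbank}} round-trips
#' to a field-identical genome. Origin-wrapping features are rendered as
#' \code{join(...)} over their normalized intervals.
#'
#' @param genome An \code{\link{annotated_genome}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_genbank <- function(genome, path) {
  stopifnot(inherits(genome, "annotated_genome"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w(sprintf("LOCUS       %-16s %d bp    DNA     %-8s UNA 01-JAN-2000",
            genome$id, genome$length, genome$topology))
  w("DEFINITION  Annotated organellar genome.")
  w(sprintf("ACCESSION   %s", genome$id))
  w("FEATURES             Location/Qualifiers")
  w(sprintf("     source          1..%d", genome$length))
  if (!is.null(genome$taxon)) {
    w(sprintf("                     /organism=\"%s\"", genome$taxon$species))
    tx <- genome$taxon
    w(sprintf(paste0("                     /note=\"taxonomy: order=%s; ",
                     "family=%s; genus=%s; subgenus=%s; section=%s\""),
              tx$order, tx$family, tx$genus, tx$subgenus, tx$section))
  }
  w(sprintf("                     /organelle=\"%s\"",
            if (genome$organelle == "mt") "mitochondrion" else "plastid"))
  for (f in genome$features) {
    key <- FEATURE_KEY_FOR_CLASS[[f$gene_class]]
    parts <- sprintf("%d..%d", f$intervals[, 1L], f$intervals[, 2L])
    loc <- if (length(parts) > 1L)
      sprintf("join(%s)", paste(parts, collapse = ",")) else parts
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    w(sprintf("     %-15s %s", key, loc))
    w(sprintf("                     /gene=\"%s\"", f$name))
    if (key == "CDS") {
      w(sprintf("                     /codon_start=%d", f$codon_start))
      w(sprintf("                     /transl_table=%d", f$transl_table))
    }
  }
  w("ORIGIN")
  s <- tolower(genome$sequence)
  for (i in seq(1L, genome$length, by = 60L)) {
    chunk <- substring(s, i, min(i + 59L, genome$length))
    blocks <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L),
                             nchar(chunk)))
    w(sprintf("%9d %s", i, paste(blocks, collapse = " ")))
  }
  w("//")
  invisible(path)
}
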