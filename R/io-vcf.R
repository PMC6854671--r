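#' Write InDel variants to a minimal VCF 4.2 file
#'
#' Events are emitted as symbolic-ALT records (`<DEL>` or `<INS>` depending
#' on `kind`) with INFO keys `END`, `SVLEN`, `MHLEN`, `INSLEN`, `BPTYPE`
#' (from [classify_breakpoint()]) plus the sequence payload needed for a
#' lossless round-trip (`DELSEQ`, `INSFRAG`, `LFLANK`, `RFLANK`, `SRC`).
#' Positions are converted to 1-based on output.
#'
#' @param variants list of [indel_variant()] objects.
#' @param path output path.
#' @param classify compute and store breakpoint annotations (default TRUE).
#' @return `path`, invisibly.
#' @export
write_indel_vcf <- function(variants, path, classify = TRUE) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=indelchip",
    "##ALT=<ID=DEL,Description=\"Deletion relative to the reference line\">",
    "##ALT=<ID=INS,Description=\"Insertion relative to the reference line\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based inclusive)\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Event length\">",
    "##INFO=<ID=MHLEN,Number=1,Type=Integer,Description=\"Microhomology length\">",
    "##INFO=<ID=INSLEN,Number=1,Type=Integer,Description=\"Non-homologous insert length\">",
    "##INFO=<ID=BPTYPE,Number=1,Type=String,Description=\"Breakpoint type I-IV\">",
    "##INFO=<ID=DELSEQ,Number=1,Type=String,Description=\"Event sequence\">",
    "##INFO=<ID=INSFRAG,Number=1,Type=String,Description=\"Inserted fragment\">",
    "##INFO=<ID=LFLANK,Number=1,Type=String,Description=\"Left flanking sequence\">",
    "##INFO=<ID=RFLANK,Number=1,Type=String,Description=\"Right flanking sequence\">",
    "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Source line\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- vapply(variants, function(v) {
    alt <- if (v$kind == "deletion_vs_ref") "<DEL>" else "<INS>"
    info <- c(sprintf("END=%d", v$end), sprintf("SVLEN=%d", nchar(v$deleted_seq)))
    if (classify) {
      bp <- classify_breakpoint(v)
      info <- c(info, sprintf("MHLEN=%d", bp$microhomology_len),
                sprintf("INSLEN=%d", bp$insert_len),
                sprintf("BPTYPE=%s", bp$type_code))
    }
    info <- c(info,
              sprintf("DELSEQ=%s", v$deleted_seq),
              sprintf("INSFRAG=%s", if (nzchar(v$inserted_fragment)) v$inserted_fragment else "."),
              sprintf("LFLANK=%s", v$left_flank),
              sprintf("RFLANK=%s", v$right_flank),
              sprintf("SRC=%s", if (is.na(v$source_line)) "." else v$source_line))
    ref <- substr(v$left_flank, nchar(v$left_flank), nchar(v$left_flank))
    if (!nzchar(ref)) ref <- "N"
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
            v$chrom, v$start, v$id, ref, alt, paste(info, collapse = ";"))
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

## parse one INFO field into a named character vector
parse_info <- function(info) {
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  setNames(vapply(kv, function(x) if (length(x) > 1L) x[2] else "", character(1)),
           vapply(kv, `[`, character(1), 1))
}

#' Read InDel variants from a VCF written by [write_indel_vcf()]
#'
#' @param path VCF path.
#' @param min_len minimum event length passed to [indel_variant()] (default 0
#'   so that toy records round-trip).
#' @return list of [indel_variant()] objects.
#' @export
read_indel_vcf <- function(path, min_len = 0L) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    info <- parse_info(f[8])
    insfrag <- info[["INSFRAG"]]
    if (is.na(insfrag) || insfrag == ".") insfrag <- ""
    src <- info[["SRC"]]
    if (is.na(src) || src == ".") src <- NA_character_
    indel_variant(
      id = f[3],
      kind = if (f[5] == "<DEL>") "deletion_vs_ref" else "insertion_vs_ref",
      chrom = f[1], start = as.integer(f[2]),
      deleted_seq = info[["DELSEQ"]],
      inserted_fragment = insfrag,
      left_flank = info[["LFLANK"]], right_flank = info[["RFLANK"]],
      source_line = src, min_len = min_len)
  })
}
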