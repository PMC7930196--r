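#' Variant calls and mitogenome profiles
#'
#' A mitogenome is represented relative to the reference as a set of variant
#' calls in rCRS coordinates. Each call is a substitution, insertion or
#' deletion; a profile couples the call set with sample metadata (age in
#' years BP, haplogroup, macrohaplogroup). Modern samples dated 2000 AD
#' carry `age_bp = -50` under the radiocarbon convention (present = 1950).
#'
#' @name profiles
NULL

#' Construct a variant table
#'
#' @param position integer vector, 1-based rCRS coordinates in
#'   `[1, 16569]`.
#' @param ref reference allele(s); `"-"` for insertions.
#' @param alt alternate allele(s); `"-"` for deletions.
#' @param kind one of `"substitution"`, `"insertion"`, `"deletion"`
#'   (recycled).
#' @return a data.frame with columns `position`, `ref`, `alt`, `kind`,
#'   ordered by position, duplicate `(position, kind, alt)` rows removed.
#' @export
variant_table <- function(position = integer(), ref = character(),
                          alt = character(), kind = "substitution") {
  n <- length(position)
  v <- data.frame(position = as.integer(position),
                  ref = rep_len(as.character(ref), n),
                  alt = rep_len(as.character(alt), n),
                  kind = rep_len(as.character(kind), n),
                  stringsAsFactors = FALSE)
  validate_variants(v)
}

validate_variants <- function(v) {
  stopifnot(is.data.frame(v),
            all(c("position", "ref", "alt", "kind") %in% names(v)))
  if (nrow(v) == 0) {
    return(v[, c("position", "ref", "alt", "kind")])
  }
  if (any(v$position < 1L | v$position > MITO_LENGTH)) {
    stop("variant positions must lie in [1, ", MITO_LENGTH, "]")
  }
  if (!all(v$kind %in% c("substitution", "insertion", "deletion"))) {
    stop("unknown variant kind: ",
         paste(setdiff(v$kind, c("substitution", "insertion", "deletion")),
               collapse = ", "))
  }
  if (any(v$ref == v$alt)) {
    stop("ref and alt alleles must differ")
  }
  if (any(v$kind == "insertion" & (v$alt == "" | v$alt == "-"))) {
    stop("insertions must carry a non-empty inserted string")
  }
  if (any(v$kind == "deletion" & (v$ref == "" | v$ref == "-"))) {
    stop("deletions must carry a non-empty deleted string")
  }
  v <- v[!duplicated(v[, c("position", "kind", "alt")]), , drop = FALSE]
  v <- v[order(v$position, v$kind), c("position", "ref", "alt", "kind")]
  rownames(v) <- NULL
  v
}

#' Construct a mitogenome profile
#'
#' @param id sample identifier.
#' @param age_bp calibrated age in years before present (1950); modern
#'   samples dated 2000 AD use -50. Must be >= -70.
#' @param haplogroup haplogroup label (PhyloTree-style), e.g. `"U5a1"`.
#' @param macrohaplogroup macrohaplogroup label; one of
#'   `c("M", "N", "R", "L-other")` unless `macro_levels` extends the set.
#' @param variants a variant table (see [variant_table()]).
#' @param macro_levels admissible macrohaplogroup labels.
#' @return an object of class `mito_profile`.
#' @export
mito_profile <- function(id, age_bp, haplogroup, macrohaplogroup,
                         variants = variant_table(),
                         macro_levels = MACRO_LEVELS) {
  stopifnot(length(id) == 1L, length(age_bp) == 1L)
  age_bp <- as.numeric(age_bp)
  if (is.na(age_bp) || age_bp < -70) {
    stop("age_bp must be >= -70 (modern = -50), got ", age_bp,
         " for sample ", id)
  }
  if (!macrohaplogroup %in% macro_levels) {
    stop("unknown macrohaplogroup '", macrohaplogroup, "' for sample ", id,
         "; admissible: ", paste(macro_levels, collapse = ", "))
  }
  structure(list(id = as.character(id), age_bp = age_bp,
                 haplogroup = as.character(haplogroup),
                 macrohaplogroup = as.character(macrohaplogroup),
                 variants = validate_variants(variants)),
            class = "mito_profile")
}

MACRO_LEVELS <- c("M", "N", "R", "L-other")

#' @export
print.mito_profile <- function(x, ...) {
  cat("<mito_profile> ", x$id, " (", x$haplogroup, "/", x$macrohaplogroup,
      "), age ", x$age_bp, " BP, ", nrow(x$variants), " variant(s)\n",
      sep = "")
  invisible(x)
}

#' Variant keys
#'
#' One token per call in the haplotype-table dialect: `73G` (substitution),
#' `309.1C` (insertion), `522d` (deletion). Two profiles share a variant
#' iff they share a key.
#'
#' @param x a `mito_profile` or variant table.
#' @return character vector of tokens.
#' @export
variant_keys <- function(x) {
  v <- if (inherits(x, "mito_profile")) x$variants else x
  if (nrow(v) == 0) {
    return(character())
  }
  ifelse(v$kind == "substitution", paste0(v$position, v$alt),
         ifelse(v$kind == "insertion", paste0(v$position, ".1", v$alt),
                paste0(v$position, "d")))
}

parse_variant_token <- function(token, reference) {
  if (grepl("^[0-9]+\\.1[ACGT]+$", token)) {
    pos <- as.integer(sub("\\.1.*$", "", token))
    variant_table(pos, "-", sub("^[0-9]+\\.1", "", token), "insertion")
  } else if (grepl("^[0-9]+d$", token)) {
    pos <- as.integer(sub("d$", "", token))
    check_pos(pos, token)
    variant_table(pos, reference$bases[pos], "-", "deletion")
  } else if (grepl("^[0-9]+[ACGT]$", token)) {
    pos <- as.integer(sub("[ACGT]$", "", token))
    check_pos(pos, token)
    alt <- substr(token, nchar(token), nchar(token))
    ref <- reference$bases[pos]
    if (ref == alt) {
      # token restates the reference base; tolerated, dropped
      return(variant_table())
    }
    variant_table(pos, ref, alt, "substitution")
  } else {
    stop("cannot parse variant token '", token, "'")
  }
}

check_pos <- function(pos, token) {
  if (is.na(pos) || pos < 1L || pos > MITO_LENGTH) {
    stop("variant token '", token, "' lies outside [1, ", MITO_LENGTH, "]")
  }
  invisible(pos)
}

#' Read profiles from aligned FASTA or a haplotype table
#'
#' FASTA mode expects pre-aligned sequences of exactly 16,569 columns; a
#' variant is called at every column that differs from the reference (gap
#' characters become deletion calls, runs of gaps are recorded once at
#' their first position; `N` and other ambiguity codes are treated as
#' missing and never called). Table mode reads the tab-delimited dialect
#' `id<TAB>token token ...` with tokens as in [variant_keys()].
#'
#' @param path FASTA file or haplotype table.
#' @param metadata_path CSV with columns `id, age_bp, haplogroup,
#'   macrohaplogroup`, one row per sequence (ids must match 1:1).
#' @param reference a [mito_reference()].
#' @param format `"fasta"`, `"table"`, or `"auto"` (by file extension:
#'   `.fa/.fasta` vs anything else).
#' @param macro_levels admissible macrohaplogroup labels.
#' @return named list of `mito_profile` objects (names = sample ids).
#' @export
read_profiles <- function(path, metadata_path,
                          reference = synthetic_reference(),
                          format = c("auto", "fasta", "table"),
                          macro_levels = MACRO_LEVELS) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "table"
  }
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  required <- c("id", "age_bp", "haplogroup", "macrohaplogroup")
  if (!all(required %in% names(meta))) {
    stop("metadata must have columns ", paste(required, collapse = ", "))
  }
  meta$id <- as.character(meta$id)
  if (anyDuplicated(meta$id)) {
    stop("duplicated metadata ids: ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  }

  calls <- if (format == "fasta") {
    read_fasta_calls(path, reference)
  } else {
    read_table_calls(path, reference)
  }

  missing_meta <- setdiff(names(calls), meta$id)
  if (length(missing_meta)) {
    stop("sequences without metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  missing_seq <- setdiff(meta$id, names(calls))
  if (length(missing_seq)) {
    stop("metadata rows without sequences: ",
         paste(missing_seq, collapse = ", "))
  }

  profiles <- lapply(meta$id, function(i) {
    row <- meta[meta$id == i, ]
    mito_profile(i, row$age_bp, row$haplogroup, row$macrohaplogroup,
                 calls[[i]], macro_levels = macro_levels)
  })
  names(profiles) <- meta$id
  profiles
}

read_fasta_calls <- function(path, reference) {
  seqs <- Biostrings::readBStringSet(path)
  widths <- Biostrings::width(seqs)
  bad <- widths != MITO_LENGTH
  if (any(bad)) {
    stop("aligned sequences must have ", MITO_LENGTH, " columns; offending: ",
         paste0(names(seqs)[bad], " (", widths[bad], ")", collapse = ", "))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  out <- lapply(seq_along(seqs), function(k) {
    call_variants(strsplit(toupper(as.character(seqs[[k]])), "")[[1]],
                  reference)
  })
  names(out) <- ids
  out
}

# Column-wise comparison of one aligned sequence against the reference.
call_variants <- function(bases, reference) {
  stopifnot(length(bases) == MITO_LENGTH)
  diff <- which(bases != reference$bases)
  if (!length(diff)) {
    return(variant_table())
  }
  is_gap <- bases[diff] %in% c("-", ".")
  is_sub <- bases[diff] %in% DNA_BASES
  subs <- diff[is_sub]
  gaps <- diff[is_gap]
  # ambiguity codes (N, R, Y, ...) at the remaining columns: missing data
  v <- variant_table(subs, reference$bases[subs], bases[subs], "substitution")
  if (length(gaps)) {
    # one deletion call per run of gaps, at the first deleted position
    starts <- gaps[c(TRUE, diff(gaps) != 1L)]
    ends <- gaps[c(diff(gaps) != 1L, TRUE)]
    dels <- variant_table(starts,
                          mapply(function(a, b) {
                            paste(reference$bases[a:b], collapse = "")
                          }, starts, ends),
                          "-", "deletion")
    v <- validate_variants(rbind(v, dels))
  }
  v
}

read_table_calls <- function(path, reference) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  out <- list()
  for (line in lines) {
    parts <- strsplit(line, "\t")[[1]]
    id <- trimws(parts[1])
    tokens <- character()
    if (length(parts) > 1) {
      tokens <- unlist(strsplit(paste(parts[-1], collapse = " "), "\\s+"))
      tokens <- tokens[nzchar(tokens)]
    }
    v <- variant_table()
    for (tok in tokens) {
      v <- rbind(v, parse_variant_token(tok, reference))
    }
    out[[id]] <- validate_variants(v)
  }
  out
}

#' Read root haplotypes from a haplotype-table file
#'
#' Each line is `label<TAB>token token ...` (tokens as in
#' [variant_keys()]); a bare label denotes the reference haplotype.
#'
#' @param path roots file.
#' @param reference a [mito_reference()].
#' @return named list of variant tables, one per root label.
#' @export
read_roots <- function(path, reference = synthetic_reference()) {
  read_table_calls(path, reference)
}

#' Write profiles in the haplotype-table dialect
#'
#' @param profiles list of `mito_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(profiles, path) {
  # one TAB after the id, spaces between tokens
  lines <- vapply(profiles, function(p) {
    keys <- variant_keys(p)
    if (length(keys)) paste0(p$id, "\t", paste(keys, collapse = " "))
    else p$id
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write profile metadata as CSV
#'
#' @inheritParams write_haplotype_table
#' @export
write_metadata <- function(profiles, path) {
  utils::write.csv(profile_metadata(profiles), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Metadata of a profile collection as a data.frame
#'
#' @param profiles list of `mito_profile`.
#' @return data.frame with columns `id, age_bp, haplogroup,
#'   macrohaplogroup, n_variants`.
#' @export
profile_metadata <- function(profiles) {
  data.frame(id = vapply(profiles, `[[`, "", "id"),
             age_bp = vapply(profiles, `[[`, 0, "age_bp"),
             haplogroup = vapply(profiles, `[[`, "", "haplogroup"),
             macrohaplogroup = vapply(profiles, `[[`, "", "macrohaplogroup"),
             n_variants = vapply(profiles, function(p) nrow(p$variants), 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Site-exclusion policy
#'
#' The default removes indel calls inside the three homopolymeric /
#' AC-repeat regions around positions 309, 522 and 16,193 (windows
#' 303-315, 513-524, 16,180-16,195) and every call at the hypermutable
#' site 16,519. Substitutions outside `excluded_sites` are never removed.
#'
#' @param indel_windows list of length-2 integer vectors, closed intervals
#'   in rCRS coordinates, within which indel calls are dropped.
#' @param excluded_sites positions at which all calls are dropped.
#' @return an object of class `exclusion_policy`.
#' @export
exclusion_policy <- function(indel_windows = list(c(303L, 315L),
                                                  c(513L, 524L),
                                                  c(16180L, 16195L)),
                             excluded_sites = 16519L) {
  for (w in indel_windows) {
    if (length(w) != 2L || w[1] > w[2] || w[1] < 1L || w[2] > MITO_LENGTH) {
      stop("each indel window must be a closed interval within [1, ",
           MITO_LENGTH, "]")
    }
  }
  structure(list(indel_windows = lapply(indel_windows, as.integer),
                 excluded_sites = as.integer(excluded_sites)),
            class = "exclusion_policy")
}

#' Apply a site-exclusion policy
#'
#' Removes indel calls whose position falls inside any indel window and
#' all calls at excluded sites. Idempotent.
#'
#' @param x a `mito_profile` or a variant table.
#' @param policy an [exclusion_policy()].
#' @return the filtered object, same class as `x`.
#' @export
apply_exclusions <- function(x, policy = exclusion_policy()) {
  if (inherits(x, "mito_profile")) {
    x$variants <- apply_exclusions(x$variants, policy)
    return(x)
  }
  v <- x
  if (!nrow(v)) {
    return(v)
  }
  in_window <- rep(FALSE, nrow(v))
  for (w in policy$indel_windows) {
    in_window <- in_window | (v$position >= w[1] & v$position <= w[2])
  }
  drop <- (v$kind %in% c("insertion", "deletion") & in_window) |
    v$position %in% policy$excluded_sites
  v[!drop, , drop = FALSE]
}

#' Pairwise mutational difference between two profiles
#'
#' The size of the symmetric difference of the two exclusion-filtered
#' variant sets. Applying the policy here is idempotent, so already
#' filtered profiles are counted identically.
#'
#' @param a,b `mito_profile` objects.
#' @param policy an [exclusion_policy()].
#' @return non-negative integer count.
#' @export
pair_difference <- function(a, b, policy = exclusion_policy()) {
  ka <- variant_keys(apply_exclusions(a$variants, policy))
  kb <- variant_keys(apply_exclusions(b$variants, policy))
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}
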