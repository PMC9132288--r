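# Reading and writing a minimal CHAT dialect: header lines ("@..."), main
# tiers ("*CHI:\t..."), dependent tiers ("%mor:\t...").  One file = one
# recording session.

#' Convert a CHAT age string to months
#'
#' CHAT `@ID` headers record the participant age as `Y;M` or `Y;M.D`
#' (years; months. days).  Ages are converted to months using a 30.44-day
#' month and rounded to two decimals, so that all downstream ages share a
#' single unit.
#'
#' @param text Character vector of CHAT age strings such as `"2;3"` or
#'   `"2;3.15"`.
#' @return Numeric vector of ages in months.
#' @examples
#' parse_age("1;0")     # 12
#' parse_age("2;0.15")  # 24.49
#' @export
parse_age <- function(text) {
  stopifnot(is.character(text))
  vapply(text, parse_age_one, numeric(1), USE.NAMES = FALSE)
}

parse_age_one <- function(x) {
  m <- regmatches(x, regexec("^([0-9]+);([0-9]+)(?:\\.([0-9]+))?$", x))[[1]]
  if (length(m) == 0) {
    stop("malformed CHAT age string: ", sQuote(x),
         " (expected Y;M or Y;M.D)", call. = FALSE)
  }
  years  <- as.integer(m[2])
  months <- as.integer(m[3])
  days   <- if (m[4] == "") 0L else as.integer(m[4])
  if (months >= 12L) {
    stop("malformed CHAT age string: ", sQuote(x),
         " (months field must be < 12)", call. = FALSE)
  }
  if (days >= 31L) {
    stop("malformed CHAT age string: ", sQuote(x),
         " (days field must be < 31)", call. = FALSE)
  }
  round(years * 12 + months + days / 30.44, 2)
}

#' Normalize a CHAT main-tier token
#'
#' Applies the tokenization rules used throughout the package: lowercase;
#' drop unintelligible / untranscribed markers (`xxx`, `yyy`, `www`),
#' fillers and fragments (tokens starting with `&`), standalone punctuation
#' and terminator codes; strip `@`-suffixes (special-form markers such as
#' `@c`, `@o`) keeping the stem; keep compound joints (`+`, `_`) so a
#' compound is one type.  Rules are conservative: they bias toward keeping
#' only real lexical types.
#'
#' @param raw Character vector of whitespace-delimited main-tier tokens.
#' @return Character vector of the same length; excluded tokens are `NA`.
#' @examples
#' normalize_token(c("Doggy@c", "choo+choo", "xxx", "&-um", "."))
#' @export
normalize_token <- function(raw) {
  stopifnot(is.character(raw))
  tok <- tolower(raw)
  # strip special-form suffix (@c child form, @o onomatopoeia, ...)
  tok <- sub("@.*$", "", tok)
  # strip surrounding angle brackets left over from retrace groups
  tok <- gsub("[<>]", "", tok)
  drop <- tok %in% c("xxx", "yyy", "www") |
    grepl("^[&+-]", tok) & !grepl("^[[:alnum:]]", tok) |
    !grepl("[[:alnum:]]", tok)
  # tokens that became empty after stripping
  drop <- drop | tok == ""
  tok[drop] <- NA_character_
  tok
}

# Split one main-tier utterance into normalized word types.
# Bracketed codes ("[!]", "[/]", "[* s:r]") are annotation, not speech.
tokenize_utterance <- function(line) {
  line <- gsub("\\[[^]]*\\]", " ", line)
  raw <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  raw <- raw[raw != ""]
  if (length(raw) == 0) return(character(0))
  tok <- normalize_token(raw)
  unique(tok[!is.na(tok)])
}

#' Parse a CHAT transcript into a session record
#'
#' Reads one CHAT document and extracts, for the target speaker, the
#' session age (from the `@ID` header) and the set of word types the
#' speaker produced on main tiers.  Tiers of all other speakers and all
#' dependent (`%`-prefixed) tiers are ignored, so the word set reflects
#' only the child's own productions.
#'
#' @param x Path to a `.cha` file, or a character vector of CHAT lines.
#' @param target_speaker Speaker code of the target child (default
#'   `"CHI"`).
#' @param child_id Child identifier; defaults to the corpus/name fields of
#'   the `@ID` header, falling back to the file name.
#' @param session_index Session number; defaults to 1 and is usually
#'   assigned by [read_chat_corpus()].
#' @return A `chat_session` list with fields `child_id`, `session_index`,
#'   `child_age_months`, `child_word_types`.
#' @export
parse_chat <- function(x, target_speaker = "CHI", child_id = NULL,
                       session_index = 1L) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    lines <- readr::read_lines(x)
    if (is.null(child_id)) {
      child_id <- sub("\\.cha$", "", basename(x))
    }
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  # tolerate a UTF-8 BOM on the first line
  if (length(lines) > 0) lines[1] <- sub("^\ufeff", "", lines[1])

  # fold tab-indented continuation lines into the preceding tier
  folded <- character(0)
  for (ln in lines) {
    if (grepl("^\\s", ln) && length(folded) > 0) {
      folded[length(folded)] <- paste(folded[length(folded)], trimws(ln))
    } else {
      folded <- c(folded, ln)
    }
  }

  id_lines <- grep("^@ID:", folded, value = TRUE)
  age <- NULL
  id_from_header <- NULL
  for (idl in id_lines) {
    fields <- strsplit(sub("^@ID:\\s*", "", idl), "|", fixed = TRUE)[[1]]
    if (length(fields) >= 4 && trimws(fields[3]) == target_speaker) {
      age <- parse_age(trimws(fields[4]))
      if (length(fields) >= 2) id_from_header <- trimws(fields[2])
    }
  }
  if (is.null(age)) {
    stop("no @ID header with an age field for speaker ",
         sQuote(target_speaker), call. = FALSE)
  }
  if (is.null(child_id)) {
    child_id <- if (!is.null(id_from_header) && nzchar(id_from_header)) {
      id_from_header
    } else {
      target_speaker
    }
  }

  tier_re <- paste0("^\\*", target_speaker, ":")
  tiers <- grep(tier_re, folded, value = TRUE)
  if (length(tiers) == 0) {
    warning("no main tier for speaker ", sQuote(target_speaker),
            " in session ", child_id, "/", session_index, call. = FALSE)
  }
  words <- unique(unlist(lapply(sub(tier_re, "", tiers), tokenize_utterance),
                         use.names = FALSE))
  new_chat_session(child_id, as.integer(session_index), age,
                   sort(words %||% character(0)))
}

new_chat_session <- function(child_id, session_index, age_months, words) {
  stopifnot(is.finite(age_months), age_months > 0)
  structure(
    list(child_id = child_id,
         session_index = session_index,
         child_age_months = age_months,
         child_word_types = words),
    class = "chat_session")
}

#' @export
print.chat_session <- function(x, ...) {
  cat(sprintf("<chat_session> child %s, session %d, age %.2f mo, %d word types\n",
              x$child_id, x$session_index, x$child_age_months,
              length(x$child_word_types)))
  invisible(x)
}

#' Serialize a session to CHAT text
#'
#' Writes the minimal dialect that [parse_chat()] reads: `@UTF8`,
#' `@Begin`, an `@ID` header carrying the age, one main tier per word
#' type, and `@End`.  Round-trips exactly through [parse_chat()].
#'
#' @param session A `chat_session`.
#' @param target_speaker Speaker code to emit (default `"CHI"`).
#' @return Character vector of CHAT lines.
#' @export
format_chat <- function(session, target_speaker = "CHI") {
  age <- months_to_age_string(session$child_age_months)
  hdr <- c(
    "@UTF8",
    "@Begin",
    "@Languages:\teng",
    sprintf("@Participants:\t%s %s Target_Child", target_speaker,
            session$child_id),
    sprintf("@ID:\teng|%s|%s|%s|||||Target_Child|||", session$child_id,
            target_speaker, age))
  tiers <- if (length(session$child_word_types) > 0) {
    sprintf("*%s:\t%s .", target_speaker, session$child_word_types)
  } else {
    character(0)
  }
  c(hdr, tiers, "@End")
}

# Inverse of parse_age to 2-decimal month precision.
months_to_age_string <- function(months) {
  years <- floor(months / 12)
  rem <- months - years * 12
  mo <- floor(rem)
  days <- round((rem - mo) * 30.44)
  if (days >= 31) { days <- 0; mo <- mo + 1 }
  if (mo >= 12) { mo <- mo - 12; years <- years + 1 }
  sprintf("%d;%d.%d", years, mo, days)
}

#' Read a directory of CHAT files as a session table
#'
#' Files are grouped into children by the subdirectory that contains them
#' (or by file-name prefix when flat), and sessions are ordered by file
#' name within each child.
#'
#' @param path Directory containing `.cha` files, possibly one
#'   subdirectory per child.
#' @param target_speaker Speaker code of the target child.
#' @return A tibble with one row per session: `child_id`,
#'   `session_index`, `age_months`, and a list-column `word_types`.
#' @export
read_chat_corpus <- function(path, target_speaker = "CHI") {
  files <- sort(list.files(path, pattern = "\\.cha$", recursive = TRUE,
                           full.names = TRUE))
  if (length(files) == 0) stop("no .cha files under ", path, call. = FALSE)
  rel <- sub(paste0("^", path, "/?"), "", files)
  child <- ifelse(dirname(rel) == ".", sub("[-_.].*$", "", basename(rel)),
                  dirname(rel))
  sessions <- vector("list", length(files))
  idx <- stats::ave(seq_along(files), child, FUN = seq_along)
  for (i in seq_along(files)) {
    sessions[[i]] <- parse_chat(files[i], target_speaker,
                                child_id = child[i],
                                session_index = idx[i])
  }
  sessions_to_table(sessions)
}

#' Convert a list of sessions to a tibble
#'
#' @param sessions List of `chat_session` objects.
#' @return Tibble with columns `child_id`, `session_index`, `age_months`,
#'   `word_types` (list-column).
#' @export
sessions_to_table <- function(sessions) {
  tab <- tibble::tibble(
    child_id = vapply(sessions, `[[`, character(1), "child_id"),
    session_index = vapply(sessions, `[[`, integer(1), "session_index"),
    age_months = vapply(sessions, `[[`, numeric(1), "child_age_months"),
    word_types = lapply(sessions, `[[`, "child_word_types"))
  dplyr::arrange(tab, .data$child_id, .data$session_index)
}

#' Long word-type listing for a session table
#'
#' @param session_table Output of [read_chat_corpus()] or
#'   [sessions_to_table()].
#' @return Tibble with one row per (session, word type): `child_id`,
#'   `session_index`, `age_months`, `word`.
#' @export
session_word_table <- function(session_table) {
  tidyr::unnest(
    dplyr::mutate(session_table, word = .data$word_types,
                  word_types = NULL),
    "word")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
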