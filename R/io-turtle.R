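# Minimal Turtle reader, convenience dialect only (RDF/XML is canonical).
# Supports @prefix declarations, <IRI> and prefixed-name terms, the 'a'
# keyword, plain/typed/language-tagged double-quoted literals, and the
# '.', ';' and ',' statement punctuation. No collections, no blank-node
# property lists, no multi-line literals.

.ttl_tokenize <- function(text) {
  tokens <- character()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch %in% c(" ", "\t", "\n", "\r")) {
      i <- i + 1L
    } else if (ch == "#") {
      while (i <= n && substr(text, i, i) != "\n") i <- i + 1L
    } else if (ch == "<") {
      j <- regexpr(">", substr(text, i, n), fixed = TRUE)
      if (j < 0) abort("Turtle parse error: unterminated IRI")
      tokens <- c(tokens, substr(text, i, i + j - 1L))
      i <- i + j
    } else if (ch == "\"") {
      j <- i + 1L
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\") j <- j + 2L
        else if (cj == "\"") break
        else j <- j + 1L
      }
      if (j > n) abort("Turtle parse error: unterminated literal")
      # attach ^^<dt> or @lang suffix to the literal token
      k <- j + 1L
      if (substr(text, k, k + 1L) == "^^") {
        m <- regexpr(">", substr(text, k, n), fixed = TRUE)
        if (m < 0) abort("Turtle parse error: unterminated datatype IRI")
        k <- k + m
      } else if (substr(text, k, k) == "@") {
        while (k <= n && grepl("[A-Za-z0-9@\\-]", substr(text, k, k))) {
          k <- k + 1L
        }
        k <- k - 1L + 1L
      }
      tokens <- c(tokens, substr(text, i, k - 1L))
      i <- k
    } else if (ch %in% c(".", ";", ",")) {
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else {
      j <- i
      while (j <= n && !grepl("[ \t\r\n;,]", substr(text, j, j)) &&
             !(substr(text, j, j) == "." && (j == n ||
               grepl("[ \t\r\n]", substr(text, j + 1L, j + 1L))))) {
        j <- j + 1L
      }
      tokens <- c(tokens, substr(text, i, j - 1L))
      i <- j
    }
  }
  tokens
}

.ttl_unescape <- function(x) {
  x <- gsub("\\\\\"", "\"", x)
  x <- gsub("\\\\n", "\n", x)
  x <- gsub("\\\\t", "\t", x)
  gsub("\\\\\\\\", "\\\\", x)
}

#' Read a BioPAX document in Turtle (secondary dialect)
#'
#' @param path Path to a `.ttl` file.
#' @return A [biopax_graph()].
#' @export
read_biopax_turtle <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Cannot read Turtle document: no such file: ", path))
  }
  text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                collapse = "\n")
  tokens <- .ttl_tokenize(text)
  prefixes <- character()

  term <- function(tok) {
    # returns list(value, lit, dt, lang)
    if (startsWith(tok, "<")) {
      return(list(v = substr(tok, 2L, nchar(tok) - 1L), lit = FALSE,
                  dt = NA_character_, lang = NA_character_))
    }
    if (startsWith(tok, "\"")) {
      close_q <- regexpr("\"[^\"]*$", tok)
      body <- substr(tok, 2L, close_q - 1L)
      rest <- substr(tok, close_q + 1L, nchar(tok))
      dt <- NA_character_
      lang <- NA_character_
      if (startsWith(rest, "^^<")) {
        dt <- substr(rest, 4L, nchar(rest) - 1L)
      } else if (startsWith(rest, "@")) {
        lang <- substring(rest, 2L)
      }
      return(list(v = .ttl_unescape(body), lit = TRUE, dt = dt, lang = lang))
    }
    if (tok == "a") {
      return(list(v = RDF_TYPE, lit = FALSE, dt = NA_character_,
                  lang = NA_character_))
    }
    parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
    pfx <- parts[1]
    if (!pfx %in% names(prefixes)) {
      abort(paste0("Turtle parse error: undeclared prefix '", pfx, ":'"))
    }
    list(v = paste0(prefixes[[pfx]],
                    paste(parts[-1], collapse = ":")),
         lit = FALSE, dt = NA_character_, lang = NA_character_)
  }

  rows <- list()
  i <- 1L
  while (i <= length(tokens)) {
    if (tokens[i] %in% c("@prefix", "PREFIX")) {
      pfx <- sub(":$", "", tokens[i + 1L])
      iri <- substr(tokens[i + 2L], 2L, nchar(tokens[i + 2L]) - 1L)
      prefixes[pfx] <- iri
      i <- i + 3L
      if (i <= length(tokens) && tokens[i] == ".") i <- i + 1L
      next
    }
    subj <- term(tokens[i])$v
    i <- i + 1L
    repeat {
      pred <- term(tokens[i])$v
      i <- i + 1L
      repeat {
        obj <- term(tokens[i])
        i <- i + 1L
        rows[[length(rows) + 1L]] <-
          list(subj, pred, obj$v, obj$lit, obj$dt, obj$lang)
        if (i > length(tokens) || tokens[i] != ",") break
        i <- i + 1L
      }
      if (i > length(tokens) || tokens[i] != ";") break
      i <- i + 1L
      if (i <= length(tokens) && tokens[i] == ".") break
    }
    if (i <= length(tokens) && tokens[i] == ".") i <- i + 1L
  }

  tr <- if (length(rows) == 0) {
    .empty_triples()
  } else {
    rdf_triples(
      subject = vapply(rows, function(r) r[[1]], ""),
      predicate = vapply(rows, function(r) r[[2]], ""),
      object = vapply(rows, function(r) r[[3]], ""),
      object_is_literal = vapply(rows, function(r) r[[4]], TRUE),
      datatype = vapply(rows, function(r) r[[5]], ""),
      lang = vapply(rows, function(r) r[[6]], "")
    )
  }
  extra <- prefixes[!names(prefixes) %in% names(DEFAULT_NAMESPACES)]
  g <- biopax_graph(tr, namespaces = extra, check_vocabulary = FALSE)
  validate_biopax_graph(g, on_unknown_predicate = "warn")
  g
}
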