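# SELFIES-style robust tokenization of molecules.
#
# A self-contained codec in the spirit of SELFIES: every molecule maps to a
# token sequence, and every token sequence decodes to a syntactically valid
# structure because bond orders are capped by the remaining valence of the
# atoms involved and malformed control tokens are ignored rather than
# rejected.  The grammar is this package's own (it is not byte-compatible
# with the reference SELFIES library); round-tripping is defined as equality
# of RDKit canonical SMILES after encode -> decode.
#
# Token grammar
#   atom    [<b><Elem>H<n><sign><c>]   b in {"", "=", "#"}: bond to parent;
#                                      n: explicit hydrogen count;
#                                      c: formal charge magnitude
#   branch  [Branch<k>] D...           k digit tokens give the branch length
#                                      (in tokens); the branch body follows
#   ring    [<b>Ring<k>] D...          k digit tokens give how many placed
#                                      atoms back the closure bond reaches
#   digits  [D0] .. [D15]              big-endian base-16 payload
#   [LINK]                             separates the components of salts and
#                                      co-crystals inside one sequence
#   [PAD]                              inert filler used by one-hot encoding
#
# Molecules are kekulized before encoding so all bond orders are integral;
# aromaticity is re-perceived by RDKit at canonicalization time.

TOK_PAD <- "[PAD]"
TOK_LINK <- "[LINK]"

.atom_rx <- "^\\[(=|#)?([A-Z][a-z]?)H([0-9]+)([+-][0-9]+)?\\]$"
.ring_rx <- "^\\[(=|#)?Ring([0-9]+)\\]$"
.branch_rx <- "^\\[Branch([0-9]+)\\]$"
.digit_rx <- "^\\[D([0-9]+)\\]$"

# Nominal maximum valences used only to cap bond orders during decoding.
.base_valence <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 5, S = 6,
                   Cl = 1, Br = 1, I = 1, Se = 6, As = 5, Te = 6)

.eff_valence <- function(elem, charge) {
  base <- .base_valence[elem]
  if (is.na(base)) base <- 8
  unname(base + abs(charge))
}

.bond_prefix <- c("", "=", "#")

.digits16 <- function(x) {
  # big-endian base-16 digit vector, at least one digit
  if (x == 0) return(0L)
  d <- integer(0)
  while (x > 0) { d <- c(x %% 16L, d); x <- x %/% 16L }
  d
}

.digit_tokens <- function(x) sprintf("[D%d]", .digits16(as.integer(x)))

.atom_token <- function(elem, charge, nH, order) {
  chg <- if (charge > 0) paste0("+", charge) else if (charge < 0) paste0("-", -charge) else ""
  sprintf("[%s%sH%d%s]", .bond_prefix[order], elem, nH, chg)
}

.parse_atom_token <- function(tok) {
  m <- regmatches(tok, regexec(.atom_rx, tok))[[1]]
  if (length(m) == 0) return(NULL)
  order <- match(m[2], c("", "=", "#"))
  charge <- if (nzchar(m[5])) as.integer(m[5]) else 0L
  list(elem = m[3], nH = as.integer(m[4]), charge = charge, order = order)
}

is_atom_token <- function(tok) grepl(.atom_rx, tok)

# ---------------------------------------------------------------------------
# encoding: kekulized graph -> tokens

encode_component_graph <- function(g) {
  n <- nrow(g$atoms)
  if (n == 0L) return(character(0))
  adj <- vector("list", n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a[k]; b <- g$bonds$b[k]; o <- g$bonds$order[k]
      adj[[a]] <- rbind(adj[[a]], c(b, o))
      adj[[b]] <- rbind(adj[[b]], c(a, o))
    }
  }
  for (i in seq_len(n)) {
    if (!is.null(adj[[i]])) adj[[i]] <- adj[[i]][order(adj[[i]][, 1]), , drop = FALSE]
  }
  pos <- integer(n)                     # placement order, 0 = unplaced
  counter <- 0L
  ring_seen <- new.env(parent = emptyenv())
  edge_key <- function(a, b) paste(min(a, b), max(a, b))

  emit <- function(v, order_from_parent, parent) {
    counter <<- counter + 1L
    pos[v] <<- counter
    toks <- .atom_token(g$atoms$elem[v], g$atoms$charge[v], g$atoms$nH[v],
                        order_from_parent)
    nb <- adj[[v]]
    if (!is.null(nb)) {
      # ring closures to atoms already placed (excluding the tree edge)
      for (k in seq_len(nrow(nb))) {
        u <- nb[k, 1]; o <- nb[k, 2]
        if (u != parent && pos[u] > 0L) {
          key <- edge_key(u, v)
          if (is.null(ring_seen[[key]])) {
            ring_seen[[key]] <- TRUE
            delta <- pos[v] - pos[u] - 1L
            dt <- .digit_tokens(delta)
            toks <- c(toks,
                      sprintf("[%sRing%d]", .bond_prefix[o], length(dt)), dt)
          }
        }
      }
      # children: unplaced neighbours at visit time, ascending index
      kids <- list()
      for (k in seq_len(nrow(nb))) {
        u <- nb[k, 1]; o <- nb[k, 2]
        if (pos[u] == 0L) kids[[length(kids) + 1L]] <- emit(u, o, v)
      }
      nk <- length(kids)
      if (nk > 0L) {
        if (nk > 1L) for (i in seq_len(nk - 1L)) {
          body <- kids[[i]]
          dt <- .digit_tokens(length(body))
          toks <- c(toks, sprintf("[Branch%d]", length(dt)), dt, body)
        }
        toks <- c(toks, kids[[nk]])
      }
    }
    toks
  }
  emit(1L, 1L, 0L)
}

#' Encode molecules as SELFIES-style token sequences
#'
#' Splits each SMILES into dot-separated components, orders components by
#' descending heavy-atom count (so salt order in the input file cannot change
#' the representation), encodes each component from its kekulized graph and
#' joins them with the reserved `[LINK]` token.
#'
#' @param smiles character vector of SMILES strings.
#' @return a list with one element per molecule: either a character vector of
#'   tokens, or `NULL` with attribute handling via the `ok` vector in the
#'   enclosing library when a component cannot be encoded.
#' @export
to_selfies <- function(smiles) {
  comps <- strsplit(smiles, ".", fixed = TRUE)
  flat <- unlist(comps, use.names = FALSE)
  if (length(flat) == 0L) return(rep(list(NULL), length(smiles)))
  graphs <- molecular_graphs(flat)
  idx <- 0L
  lapply(seq_along(smiles), function(i) {
    k <- length(comps[[i]])
    gs <- graphs[(idx + 1L):(idx + k)]
    idx <<- idx + k
    if (any(vapply(gs, is.null, TRUE))) return(NULL)
    heavy <- vapply(gs, function(g) g$heavy, 0L)
    gs <- gs[order(-heavy)]
    parts <- lapply(gs, encode_component_graph)
    toks <- parts[[1]]
    if (length(parts) > 1L) {
      for (p in parts[-1]) toks <- c(toks, TOK_LINK, p)
    }
    toks
  })
}

# ---------------------------------------------------------------------------
# decoding: tokens -> graph -> SMILES

decode_component_tokens <- function(toks) {
  atoms <- list(elem = character(0), charge = integer(0), nH = integer(0))
  bonds <- matrix(numeric(0), ncol = 3)
  used <- numeric(0)                    # valence consumed per atom
  placed <- integer(0)

  cap <- function(i) {
    .eff_valence(atoms$elem[i], atoms$charge[i]) - atoms$nH[i] - used[i]
  }
  add_atom <- function(info) {
    atoms$elem <<- c(atoms$elem, info$elem)
    atoms$charge <<- c(atoms$charge, info$charge)
    atoms$nH <<- c(atoms$nH, info$nH)
    used <<- c(used, 0)
    id <- length(used)
    placed <<- c(placed, id)
    id
  }
  add_bond <- function(a, b, o) {
    o <- min(o, cap(a), cap(b))
    if (a == b || o < 1) return(FALSE)
    if (nrow(bonds) && any(pmin(bonds[, 1], bonds[, 2]) == min(a, b) &
                           pmax(bonds[, 1], bonds[, 2]) == max(a, b))) return(FALSE)
    bonds <<- rbind(bonds, c(a, b, o))
    used[a] <<- used[a] + o; used[b] <<- used[b] + o
    TRUE
  }
  read_digits <- function(toks, i, k) {
    # reads up to k digit tokens starting at i; returns list(value, consumed)
    val <- 0L; consumed <- 0L
    while (consumed < k && i + consumed <= length(toks)) {
      m <- regmatches(toks[i + consumed], regexec(.digit_rx, toks[i + consumed]))[[1]]
      if (length(m) == 0) break
      val <- val * 16L + as.integer(m[2])
      consumed <- consumed + 1L
    }
    list(value = val, consumed = consumed)
  }

  parse <- function(toks, parent) {
    cur <- parent
    i <- 1L
    while (i <= length(toks)) {
      t <- toks[i]
      info <- .parse_atom_token(t)
      if (!is.null(info)) {
        if (cur == 0L) {
          cur <- add_atom(info)
        } else {
          o <- min(info$order, cap(cur))
          if (o >= 1) {
            id <- add_atom(info)
            add_bond(cur, id, o)
            cur <- id
          }                              # else: parent saturated, atom dropped
        }
        i <- i + 1L
      } else if (grepl(.branch_rx, t)) {
        k <- as.integer(sub(.branch_rx, "\\1", t))
        rd <- read_digits(toks, i + 1L, k)
        len <- rd$value
        body_from <- i + 1L + rd$consumed
        body_to <- min(length(toks), body_from + len - 1L)
        if (cur > 0L && len > 0L && body_from <= body_to) {
          parse(toks[body_from:body_to], cur)
        }
        i <- body_to + 1L
      } else if (grepl(.ring_rx, t)) {
        m <- regmatches(t, regexec(.ring_rx, t))[[1]]
        o <- match(m[2], c("", "=", "#"))
        k <- as.integer(m[3])
        rd <- read_digits(toks, i + 1L, k)
        if (cur > 0L) {
          tgt_idx <- length(placed) - 1L - rd$value
          if (tgt_idx >= 1L) add_bond(cur, placed[tgt_idx], o)
        }
        i <- i + 1L + rd$consumed
      } else {
        i <- i + 1L                      # [PAD], stray digits, unknown: inert
      }
    }
  }
  parse(toks, 0L)
  if (length(atoms$elem) == 0L) return(NULL)
  list(atoms = data.frame(elem = atoms$elem, charge = atoms$charge,
                          nH = atoms$nH, stringsAsFactors = FALSE),
       bonds = if (nrow(bonds)) data.frame(a = as.integer(bonds[, 1]),
                                           b = as.integer(bonds[, 2]),
                                           order = as.integer(bonds[, 3]))
               else data.frame(a = integer(0), b = integer(0), order = integer(0)))
}

.bond_sym <- c("", "=", "#")

write_component_smiles <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a[k]; b <- g$bonds$b[k]; o <- g$bonds$order[k]
      adj[[a]] <- rbind(adj[[a]], c(b, o))
      adj[[b]] <- rbind(adj[[b]], c(a, o))
    }
  }
  atom_str <- function(v) {
    e <- g$atoms$elem[v]; h <- g$atoms$nH[v]; c0 <- g$atoms$charge[v]
    hs <- if (h == 0) "" else if (h == 1) "H" else paste0("H", h)
    cs <- if (c0 == 0) "" else if (c0 == 1) "+" else if (c0 == -1) "-" else
      if (c0 > 0) paste0("+", c0) else paste0("-", -c0)
    paste0("[", e, hs, cs, "]")
  }
  visited <- logical(n)
  ring_num <- 0L
  ring_open <- vector("list", n)        # per atom: list of c(number, order, first)
  ring_assigned <- new.env(parent = emptyenv())
  # pre-walk to find back edges and assign closure numbers at both endpoints
  prewalk <- function(v, parent) {
    visited[v] <<- TRUE
    nb <- adj[[v]]
    if (is.null(nb)) return(invisible())
    for (k in seq_len(nrow(nb))) {
      u <- nb[k, 1]; o <- nb[k, 2]
      key <- paste(min(u, v), max(u, v))
      if (!visited[u]) {
        if (is.null(ring_assigned[[key]])) {
          ring_assigned[[key]] <- -1L   # tree edge
          prewalk(u, v)
        }
      } else if (u != parent && identical(ring_assigned[[key]], NULL)) {
        ring_num <<- ring_num + 1L
        ring_assigned[[key]] <- ring_num
        ring_open[[u]] <<- rbind(ring_open[[u]], c(ring_num, o, 1L))
        ring_open[[v]] <<- rbind(ring_open[[v]], c(ring_num, o, 0L))
      }
    }
  }
  prewalk(1L, 0L)
  ring_digit <- function(num) if (num < 10) as.character(num) else sprintf("%%%02d", num)
  visited2 <- logical(n)
  build <- function(v, order_from_parent) {
    visited2[v] <<- TRUE
    s <- paste0(.bond_sym[order_from_parent], atom_str(v))
    ro <- ring_open[[v]]
    if (!is.null(ro)) for (k in seq_len(nrow(ro))) {
      pre <- if (ro[k, 3] == 1L) .bond_sym[ro[k, 2]] else ""
      s <- paste0(s, pre, ring_digit(ro[k, 1]))
    }
    nb <- adj[[v]]
    if (!is.null(nb)) {
      kids <- list()
      for (k in seq_len(nrow(nb))) {
        u <- nb[k, 1]; o <- nb[k, 2]
        key <- paste(min(u, v), max(u, v))
        if (!visited2[u] && identical(ring_assigned[[key]], -1L)) {
          kids[[length(kids) + 1L]] <- build(u, o)
        }
      }
      nk <- length(kids)
      if (nk > 0L) {
        if (nk > 1L) for (i in seq_len(nk - 1L)) s <- paste0(s, "(", kids[[i]], ")")
        s <- paste0(s, kids[[nk]])
      }
    }
    s
  }
  build(1L, 1L)
}

#' Decode a SELFIES-style token sequence back to SMILES
#'
#' Total on any token vector over the grammar: bond orders are capped by
#' remaining valence, malformed control tokens are skipped, and an empty
#' derivation falls back to methane so a structure is always produced.
#'
#' @param tokens character vector of tokens (possibly containing `[LINK]`).
#' @return a single SMILES string (components joined with `.`).
#' @export
from_selfies <- function(tokens) {
  if (length(tokens) == 0L) return("C")
  tokens <- tokens[tokens != TOK_PAD]
  comps <- split(tokens, cumsum(tokens == TOK_LINK))
  comps <- lapply(comps, function(x) x[x != TOK_LINK])
  out <- character(0)
  for (cc in comps) {
    if (length(cc) == 0L) next
    gg <- decode_component_tokens(cc)
    if (is.null(gg)) next
    out <- c(out, write_component_smiles(gg))
  }
  if (length(out) == 0L) return("C")
  paste(out, collapse = ".")
}

# ---------------------------------------------------------------------------
# vocabulary and one-hot flattening

#' Build a token vocabulary over a set of token sequences
#'
#' @param token_lists list of character token vectors (NULLs are skipped).
#' @param extra additional tokens guaranteed to be present.
#' @return an object of class `token_vocabulary` with the ordered unique
#'   token list (`[PAD]` first, then `[LINK]`) and the maximum sequence
#'   length observed.
#' @export
build_vocabulary <- function(token_lists, extra = character(0)) {
  token_lists <- token_lists[!vapply(token_lists, is.null, TRUE)]
  toks <- sort(unique(c(unlist(token_lists, use.names = FALSE), extra)))
  toks <- setdiff(toks, c(TOK_PAD, TOK_LINK))
  tokens <- c(TOK_PAD, TOK_LINK, toks)
  max_len <- if (length(token_lists)) max(lengths(token_lists)) else 0L
  structure(list(tokens = tokens, max_len = as.integer(max_len),
                 index = stats::setNames(seq_along(tokens), tokens)),
            class = "token_vocabulary")
}

#' @export
print.token_vocabulary <- function(x, ...) {
  cat("<token_vocabulary>", length(x$tokens), "tokens, max_len", x$max_len, "\n")
  invisible(x)
}

#' One-hot encode a token sequence
#'
#' Flattens to a binary vector of length `max_len * |tokens|`; positions past
#' the sequence are set to the `[PAD]` token so exactly `max_len` entries are
#' hot.
#'
#' @param tokens character token vector of length at most `vocab$max_len`.
#' @param vocab a [build_vocabulary()] result.
#' @return numeric 0/1 vector.
#' @export
one_hot_encode <- function(tokens, vocab) {
  nv <- length(vocab$tokens)
  if (length(tokens) > vocab$max_len) {
    stop("sequence longer than vocabulary max_len")
  }
  ids <- vocab$index[tokens]
  if (anyNA(ids)) {
    stop("out-of-vocabulary token: ",
         paste(tokens[is.na(ids)], collapse = ", "))
  }
  ids <- c(unname(ids), rep(vocab$index[[TOK_PAD]], vocab$max_len - length(tokens)))
  v <- numeric(vocab$max_len * nv)
  v[(seq_len(vocab$max_len) - 1L) * nv + ids] <- 1
  v
}

#' Invert [one_hot_encode()]
#'
#' @param v flat 0/1 (or score) vector of length `max_len * |tokens|`; per
#'   position the arg-max token is taken, so the function also serves as the
#'   greedy read-out for decoder logits.
#' @param vocab the vocabulary used for encoding.
#' @param strip_pad drop trailing `[PAD]` tokens (default `TRUE`).
#' @return character token vector.
#' @export
one_hot_decode <- function(v, vocab, strip_pad = TRUE) {
  nv <- length(vocab$tokens)
  stopifnot(length(v) == vocab$max_len * nv)
  m <- matrix(v, nrow = nv)
  ids <- apply(m, 2, which.max)
  toks <- vocab$tokens[ids]
  if (strip_pad) {
    keep <- rev(cumsum(rev(toks != TOK_PAD)) > 0)
    toks <- toks[keep]
  }
  toks
}
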