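# Text grammar for the bounded-time logic.
#
#   property  := prob | reward | mqd
#   prob      := 'P' cmpq '[' path ']'
#   reward    := 'R' '{' '"' name '"' '}' cmpq '[' 'C' window ']'
#   mqd       := 'MQD' '{' ident '}' cmpq '[' 'T' '=' number ']'
#   cmpq      := '=?' | ('>='|'<='|'>'|'<') number
#   path      := 'G' interval state | state 'U' interval state
#   interval  := '[' number ',' number ']'   (finite bounds only)
#   window    := '<=' number | '[' number ',' number ']'
#   state     := disjunctions/conjunctions/negations of comparisons
#                (ident cmp integer), 'true', 'false', named labels,
#                parentheses, nested 'P' operators with thresholds
#
# Examples: P=? [ true U[1000,1000] (X>=15 & X<=20) ]
#           P>=0.9 [ G[0,600] high ]
#           R{"low"}=? [ C<=1000 ]      MQD{Rp}=? [ T=20000 ]

tokenize_property <- function(text) {
  pats <- c(num = "^[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?",
            op = "^(=\\?|>=|<=|>|<|=|&|\\||!|\\[|\\]|\\(|\\)|\\{|\\}|,)",
            ident = "^[A-Za-z_][A-Za-z0-9_]*",
            str = '^"[^"]*"')
  toks <- list(); pos <- 1L
  s <- text
  while (nchar(s) > 0) {
    ws <- regmatches(s, regexpr("^\\s+", s))
    if (length(ws)) { pos <- pos + nchar(ws); s <- substring(s, nchar(ws) + 1L) }
    if (nchar(s) == 0) break
    matched <- FALSE
    for (ty in names(pats)) {
      m <- regmatches(s, regexpr(pats[[ty]], s))
      if (length(m)) {
        toks[[length(toks) + 1L]] <- list(type = ty, value = m, pos = pos)
        pos <- pos + nchar(m); s <- substring(s, nchar(m) + 1L)
        matched <- TRUE
        break
      }
    }
    if (!matched)
      stop("property syntax error at position ", pos, ": '",
           substring(s, 1, 10), "'", call. = FALSE)
  }
  toks
}

#' Parse a property text into a formula
#'
#' @param text Property in the documented grammar.
#' @param labels Optional named character vector resolving bare
#'   identifiers to population predicates (a network's `labels` entry is
#'   used automatically in [check_formula()] pipelines that parse with
#'   the network at hand).
#' @return A formula node as built by [prob_op()], [reward_op()] or
#'   [mqd_op()].
#' @export
parse_property <- function(text, labels = NULL) {
  toks <- tokenize_property(text)
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[[i]] else NULL
  advance <- function() { t <- toks[[i]]; i <<- i + 1L; t }
  expect <- function(value) {
    t <- peek()
    if (is.null(t) || t$value != value)
      stop("expected '", value, "' at position ",
           if (is.null(t)) nchar(text) else t$pos, call. = FALSE)
    advance()
  }
  expect_type <- function(type) {
    t <- peek()
    if (is.null(t) || t$type != type)
      stop("expected ", type, " at position ",
           if (is.null(t)) nchar(text) else t$pos, call. = FALSE)
    advance()
  }

  parse_cmpq <- function() {
    t <- peek()
    if (!is.null(t) && t$value == "=?") { advance(); return(list(cmp = "=?", r = NULL)) }
    if (!is.null(t) && t$value %in% c(">=", "<=", ">", "<")) {
      advance()
      r <- as.numeric(expect_type("num")$value)
      return(list(cmp = t$value, r = r))
    }
    stop("expected '=?' or a threshold comparison at position ",
         if (is.null(t)) nchar(text) else t$pos, call. = FALSE)
  }
  parse_interval <- function() {
    expect("[")
    t1 <- as.numeric(expect_type("num")$value)
    expect(",")
    t2 <- as.numeric(expect_type("num")$value)
    expect("]")
    if (!is.finite(t1) || !is.finite(t2))
      stop("only finite time bounds are supported", call. = FALSE)
    c(t1, t2)
  }

  parse_state <- function() parse_or()
  parse_or <- function() {
    l <- parse_and()
    while (!is.null(peek()) && peek()$value == "|") {
      advance(); l <- csl_or(l, parse_and())
    }
    l
  }
  parse_and <- function() {
    l <- parse_unary()
    while (!is.null(peek()) && peek()$value == "&") {
      advance(); l <- csl_and(l, parse_unary())
    }
    l
  }
  parse_unary <- function() {
    t <- peek()
    if (is.null(t)) stop("unexpected end of property", call. = FALSE)
    if (t$value == "!") { advance(); return(csl_not(parse_unary())) }
    if (t$value == "(") {
      advance(); f <- parse_state(); expect(")"); return(f)
    }
    if (t$type == "ident" && t$value == "P") return(parse_prob())
    if (t$type == "ident") {
      advance()
      nm <- t$value
      if (tolower(nm) %in% c("true", "false")) return(csl_atomic(tolower(nm)))
      nxt <- peek()
      if (!is.null(nxt) && nxt$value %in% c(">=", "<=", ">", "<", "=")) {
        advance()
        v <- expect_type("num")$value
        op <- if (nxt$value == "=") "==" else nxt$value
        return(csl_atomic(paste(nm, op, v)))
      }
      # bare identifier: named label
      if (!is.null(labels) && nm %in% names(labels))
        return(csl_atomic(labels[[nm]]))
      return(structure(list(type = "ap", predicate = nm, label = TRUE),
                       class = "stochrob_formula"))
    }
    stop("property syntax error at position ", t$pos, call. = FALSE)
  }
  parse_path <- function() {
    t <- peek()
    if (!is.null(t) && t$type == "ident" && t$value == "G") {
      advance()
      iv <- parse_interval()
      phi <- parse_state()
      return(path_globally(phi, iv[1], iv[2]))
    }
    phi <- parse_state()
    u <- expect_type("ident")
    if (u$value != "U") stop("expected 'U' at position ", u$pos, call. = FALSE)
    iv <- parse_interval()
    psi <- parse_state()
    path_until(phi, psi, iv[1], iv[2])
  }
  parse_prob <- function() {
    expect("P")
    cq <- parse_cmpq()
    expect("[")
    p <- parse_path()
    expect("]")
    prob_op(p, cq$cmp, cq$r)
  }
  parse_reward <- function() {
    expect("R")
    expect("{")
    nm <- expect_type("str")$value
    nm <- substr(nm, 2, nchar(nm) - 1)
    expect("}")
    cq <- parse_cmpq()
    expect("[")
    expect("C")
    t <- peek()
    if (!is.null(t) && t$value == "<=") {
      advance()
      t2 <- as.numeric(expect_type("num")$value)
      win <- c(0, t2)
    } else win <- parse_interval()
    expect("]")
    reward_op(nm, t2 = win[2], t1 = win[1], cmp = cq$cmp, r = cq$r)
  }
  parse_mqd <- function() {
    expect("MQD")
    expect("{")
    spn <- expect_type("ident")$value
    expect("}")
    cq <- parse_cmpq()
    expect("[")
    expect("T")
    expect("=")
    tt <- as.numeric(expect_type("num")$value)
    expect("]")
    mqd_op(spn, tt, cmp = cq$cmp, r = cq$r)
  }

  t0 <- peek()
  if (is.null(t0)) stop("empty property", call. = FALSE)
  out <- if (t0$value == "P") parse_prob()
  else if (t0$value == "R") parse_reward()
  else if (t0$value == "MQD") parse_mqd()
  else stop("a property starts with P, R or MQD", call. = FALSE)
  if (i <= length(toks))
    stop("trailing input at position ", toks[[i]]$pos, call. = FALSE)
  out
}

#' Pretty-print a formula in the property grammar
#'
#' Inverse of [parse_property()] up to whitespace.
#'
#' @param formula A formula node.
#' @return A single string.
#' @export
format_property <- function(formula) {
  cmpq <- function(cmp, r) if (cmp == "=?") "=?" else paste0(cmp, r)
  iv <- function(t1, t2) paste0("[", t1, ",", t2, "]")
  st <- function(f, parent = "") {
    switch(f$type,
      ap = {
        p <- f$predicate
        if (is.function(p)) stop("cannot format a function predicate",
                                 call. = FALSE)
        p <- gsub("==", "=", p, fixed = TRUE)
        if (grepl("[&|]", p)) paste0("(", p, ")") else p
      },
      not = paste0("!", wrap_tight(f$phi)),
      and = {
        s <- paste0(wrap_tight(f$phi), " & ", wrap_tight(f$psi))
        if (parent != "") paste0("(", s, ")") else s
      },
      or = {
        s <- paste0(wrap_tight(f$phi), " | ", wrap_tight(f$psi))
        if (parent != "") paste0("(", s, ")") else s
      },
      prob = fmt_prob(f),
      stop("cannot format node '", f$type, "'", call. = FALSE))
  }
  fmt_path <- function(p) {
    if (p$type == "until")
      paste0(wrap_operand(p$phi), " U", iv(p$t1, p$t2), " ",
             wrap_operand(p$psi))
    else
      paste0("G", iv(p$t1, p$t2), " ", wrap_operand(p$phi))
  }
  wrap_operand <- function(f) {
    s <- st(f)
    if (f$type %in% c("and", "or")) paste0("(", s, ")") else s
  }
  wrap_tight <- function(f) {
    s <- st(f, parent = "operand")
    if (f$type %in% c("and", "or")) s else s  # compounds already wrapped
  }
  fmt_prob <- function(f)
    paste0("P", cmpq(f$cmp, f$r), " [ ", fmt_path(f$path), " ]")
  switch(formula$type,
    prob = fmt_prob(formula),
    reward = paste0('R{"', formula$reward, '"}', cmpq(formula$cmp, formula$r),
                    " [ ",
                    if (formula$t1 == 0) paste0("C<=", formula$t2)
                    else paste0("C", iv(formula$t1, formula$t2)),
                    " ]"),
    mqd = paste0("MQD{", formula$species, "}", cmpq(formula$cmp, formula$r),
                 " [ T=", formula$t, " ]"),
    st(formula))
}
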