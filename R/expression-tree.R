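#' @title Expression trees for symbolic regression
#' @name expression-tree
#' @description
#' An expression tree is the genome of the genetic-programming regressor: a
#' rooted tree whose internal nodes carry a symbol from the function set and
#' whose leaves are either the time variable `t` or a numeric constant.
#' Trees are plain nested lists so they copy cheaply and serialize to both a
#' readable function-call text form and a nested JSON form.
NULL

#' The function set: symbol name -> arity
#'
#' Binary symbols: add, sub, mult, div, max, min. Unary symbols: sqrt, log,
#' abs, neg, inv, sin, cos, tan. Division, inverse, square root, logarithm
#' and tangent are evaluated in protected form (see [eval_tree()]), so every
#' tree is a total function of its input.
#'
#' @format Named integer vector mapping symbol to arity.
#' @export
gp_function_set <- c(
  add = 2L, sub = 2L, mult = 2L, div = 2L, max = 2L, min = 2L,
  sqrt = 1L, log = 1L, abs = 1L, neg = 1L, inv = 1L,
  sin = 1L, cos = 1L, tan = 1L
)

#' Construct expression-tree nodes
#'
#' `gp_var()` is the time-variable leaf, `gp_const(value)` a constant leaf,
#' and `gp_call(symbol, ...)` an internal node applying a function-set symbol
#' to child subtrees.
#'
#' @param value Numeric scalar for a constant leaf.
#' @param symbol One of `names(gp_function_set)`.
#' @param ... Child subtrees; their number must equal the symbol's arity.
#' @return An expression-tree node (nested list).
#' @examples
#' tree <- gp_call("add", gp_var(), gp_const(2))
#' eval_tree(tree, t = 3)
#' @export
gp_var <- function() {
  structure(list(type = "var"), class = "gp_tree")
}

#' @rdname gp_var
#' @export
gp_const <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop_validation("constant leaf requires a single finite numeric value")
  }
  structure(list(type = "const", value = as.numeric(value)), class = "gp_tree")
}

#' @rdname gp_var
#' @export
gp_call <- function(symbol, ...) {
  kids <- list(...)
  arity <- gp_function_set[symbol]
  if (is.na(arity)) {
    stop_validation(sprintf("unknown function symbol '%s'", symbol))
  }
  if (length(kids) != arity) {
    stop_validation(sprintf(
      "symbol '%s' has arity %d but received %d children",
      symbol, arity, length(kids)
    ))
  }
  structure(list(type = "call", symbol = symbol, kids = kids),
            class = "gp_tree")
}

is_leaf <- function(node) node$type != "call"

#' Count nodes / measure depth of an expression tree
#'
#' Depth is counted in edges: a single leaf has depth 0.
#'
#' @param tree An expression tree.
#' @return Integer scalar.
#' @export
node_count <- function(tree) {
  if (is_leaf(tree)) return(1L)
  1L + sum(vapply(tree$kids, node_count, integer(1)))
}

#' @rdname node_count
#' @export
tree_depth <- function(tree) {
  if (is_leaf(tree)) return(0L)
  1L + max(vapply(tree$kids, tree_depth, integer(1)))
}

#' Validate the structural invariants of an expression tree
#'
#' Checks arity of every internal node, optionally a depth bound and that
#' constant leaves fall inside a configured range. Errors on violation,
#' returns `TRUE` invisibly otherwise.
#'
#' @param tree Expression tree.
#' @param max_depth Optional depth bound (edges).
#' @param constant_range Optional length-2 numeric range for constant leaves.
#' @export
validate_tree <- function(tree, max_depth = NULL, constant_range = NULL) {
  walk <- function(node) {
    if (!is.list(node) || is.null(node$type)) {
      stop_validation("malformed tree node")
    }
    if (node$type == "const") {
      if (!is.finite(node$value)) stop_validation("non-finite constant leaf")
      if (!is.null(constant_range) &&
          (node$value < constant_range[1] || node$value > constant_range[2])) {
        stop_validation(sprintf(
          "constant %g outside configured range [%g, %g]",
          node$value, constant_range[1], constant_range[2]
        ))
      }
    } else if (node$type == "call") {
      arity <- gp_function_set[node$symbol]
      if (is.na(arity)) {
        stop_validation(sprintf("unknown function symbol '%s'", node$symbol))
      }
      if (length(node$kids) != arity) {
        stop_validation(sprintf(
          "symbol '%s' has %d children, expected %d",
          node$symbol, length(node$kids), arity
        ))
      }
      for (k in node$kids) walk(k)
    } else if (node$type != "var") {
      stop_validation(sprintf("unknown node type '%s'", node$type))
    }
  }
  walk(tree)
  if (!is.null(max_depth) && tree_depth(tree) > max_depth) {
    stop_validation(sprintf(
      "tree depth %d exceeds max_depth %d", tree_depth(tree), max_depth
    ))
  }
  invisible(TRUE)
}

#' Evaluate an expression tree at given inputs
#'
#' Recursive evaluation with protected operators so the result is finite for
#' any finite input: `div(a, b)` returns 1 where `|b| <= eps`; `inv(a)`
#' returns 1 where `|a| <= eps`; `sqrt(a) = sqrt(|a|)`; `log(a) = ln|a|`
#' where `|a| > eps`, else 0; `tan` is clamped to `[-1e6, 1e6]`.
#'
#' @param tree Expression tree.
#' @param t Numeric vector of (scaled) time values.
#' @param eps Protection threshold for near-zero denominators/arguments.
#' @return Numeric vector, same length as `t`.
#' @export
eval_tree <- function(tree, t, eps = 1e-6) {
  t <- as.numeric(t)
  if (tree$type == "var") return(t)
  if (tree$type == "const") return(rep.int(tree$value, length(t)))
  a <- eval_tree(tree$kids[[1L]], t, eps)
  switch(tree$symbol,
    add  = a + eval_tree(tree$kids[[2L]], t, eps),
    sub  = a - eval_tree(tree$kids[[2L]], t, eps),
    mult = a * eval_tree(tree$kids[[2L]], t, eps),
    div  = {
      b <- eval_tree(tree$kids[[2L]], t, eps)
      ifelse(abs(b) > eps, a / b, 1)
    },
    max  = pmax(a, eval_tree(tree$kids[[2L]], t, eps)),
    min  = pmin(a, eval_tree(tree$kids[[2L]], t, eps)),
    sqrt = sqrt(abs(a)),
    log  = ifelse(abs(a) > eps, log(abs(a)), 0),
    abs  = abs(a),
    neg  = -a,
    inv  = ifelse(abs(a) > eps, 1 / a, 1),
    sin  = sin(a),
    cos  = cos(a),
    tan  = pmin(pmax(tan(a), -1e6), 1e6),
    stop_validation(sprintf("unknown function symbol '%s'", tree$symbol))
  )
}

format_gp_constant <- function(value) {
  s <- format(value, digits = 17, scientific = FALSE, trim = TRUE)
  if (!grepl("[.eE]", s)) s <- paste0(s, ".0")
  s
}

#' Serialize an expression tree to text / parse it back
#'
#' The text grammar is function-call notation over the function-set symbol
#' names, e.g. `"add(t, 2.0)"`. Constants print with 17 significant digits so
#' a round trip preserves evaluation exactly.
#'
#' @param tree Expression tree.
#' @return `to_infix()`: a character scalar. `parse_infix()`: an expression
#'   tree.
#' @examples
#' txt <- to_infix(gp_call("add", gp_var(), gp_const(2)))
#' eval_tree(parse_infix(txt), 3)
#' @export
to_infix <- function(tree) {
  if (tree$type == "var") return("t")
  if (tree$type == "const") return(format_gp_constant(tree$value))
  args <- vapply(tree$kids, to_infix, character(1))
  paste0(tree$symbol, "(", paste(args, collapse = ", "), ")")
}

#' @rdname to_infix
#' @param text Character scalar in the serialization grammar.
#' @export
parse_infix <- function(text) {
  if (!is.character(text) || length(text) != 1L) {
    stop_validation("parse_infix expects a single character string")
  }
  src <- text
  pos <- 1L
  n <- nchar(src)

  skip_ws <- function() {
    while (pos <= n && substr(src, pos, pos) %in% c(" ", "\t", "\n")) {
      pos <<- pos + 1L
    }
  }
  fail <- function(msg) {
    stop_validation(sprintf("parse error at position %d: %s", pos, msg))
  }
  peek <- function() if (pos <= n) substr(src, pos, pos) else ""

  parse_expr <- function() {
    skip_ws()
    if (pos > n) fail("unexpected end of input")
    ch <- peek()
    if (grepl("[A-Za-z_]", ch)) {
      m <- regmatches(
        substr(src, pos, n),
        regexpr("^[A-Za-z_][A-Za-z0-9_]*", substr(src, pos, n))
      )
      name <- m[[1]]
      pos <<- pos + nchar(name)
      skip_ws()
      if (peek() == "(") {
        arity <- gp_function_set[name]
        if (is.na(arity)) fail(sprintf("unknown symbol '%s'", name))
        pos <<- pos + 1L
        kids <- list(parse_expr())
        skip_ws()
        while (peek() == ",") {
          pos <<- pos + 1L
          kids <- c(kids, list(parse_expr()))
          skip_ws()
        }
        if (peek() != ")") fail("expected ')' or ','")
        pos <<- pos + 1L
        if (length(kids) != arity) {
          fail(sprintf("symbol '%s' expects %d arguments, got %d",
                       name, arity, length(kids)))
        }
        do.call(gp_call, c(list(name), kids))
      } else if (name == "t") {
        gp_var()
      } else {
        fail(sprintf("unknown symbol '%s'", name))
      }
    } else if (grepl("[0-9+.-]", ch)) {
      m <- regmatches(
        substr(src, pos, n),
        regexpr("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?",
                substr(src, pos, n))
      )
      if (length(m) == 0L || nchar(m[[1]]) == 0L) fail("invalid number")
      pos <<- pos + nchar(m[[1]])
      gp_const(as.numeric(m[[1]]))
    } else {
      fail(sprintf("unexpected character '%s'", ch))
    }
  }

  tree <- parse_expr()
  skip_ws()
  if (pos <= n) fail("trailing input after expression")
  tree
}

#' Convert an expression tree to/from its nested JSON form
#'
#' Internal nodes serialize as `{"symbol": ..., "children": [...]}`, the
#' time variable as `{"symbol": "t"}` and constants as `{"value": ...}`.
#'
#' @param tree Expression tree.
#' @return `tree_to_json()`: a JSON character scalar; `tree_from_json()`:
#'   an expression tree.
#' @export
tree_to_json <- function(tree) {
  # constants are written with 17 significant digits so the nearest-double
  # parse recovers them exactly
  as_json <- function(node) {
    if (node$type == "var") return('{"symbol":"t"}')
    if (node$type == "const") {
      return(sprintf('{"value":%s}',
                     formatC(node$value, digits = 17, format = "g")))
    }
    sprintf('{"symbol":"%s","children":[%s]}', node$symbol,
            paste(vapply(node$kids, as_json, character(1)), collapse = ","))
  }
  as_json(tree)
}

#' @rdname tree_to_json
#' @param json JSON character scalar.
#' @export
tree_from_json <- function(json) {
  from_list <- function(x) {
    if (!is.null(x$value)) return(gp_const(x$value))
    if (is.null(x$symbol)) stop_validation("JSON node lacks symbol and value")
    if (x$symbol == "t" && is.null(x$children)) return(gp_var())
    do.call(gp_call, c(list(x$symbol), lapply(x$children, from_list)))
  }
  from_list(jsonlite::fromJSON(json, simplifyVector = FALSE))
}

#' @export
print.gp_tree <- function(x, ...) {
  cat("<expression tree> ", to_infix(x), "\n", sep = "")
  invisible(x)
}
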