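#' Build a k-Tasks allocation scheme for a five-user group
#'
#' Division-of-work task allocation: each of the five users receives an
#' instruction subset of size `k` that always contains the reference
#' instruction (both feet by default, the class with the weakest ERD and
#' hence the most separable "rest-like" task). Subsets are built cyclically:
#' the five non-reference instructions, in ascending order, are labelled
#' 0..4 and user `u` (0-based) receives the reference plus labels
#' `(u + m) mod 5` for `m = 0..k-2`. This balanced design gives every
#' non-reference instruction to exactly `k - 1` users and degenerates to the
#' common-work strategy at `k = 6` (every user holds all six instructions).
#'
#' @param k Tasks per user, 2-6.
#' @param reference Reference instruction (default 2, both feet).
#' @param n_users Number of collaborators (fixed at 5 by the design).
#' @param instructions Full instruction set (default 1:6).
#' @return A list of class `allocation_scheme`: `k`, `reference`, `users`
#'   (LETTERS A-E), `subsets` (named list user -> sorted instruction set).
#' @export
build_scheme <- function(k, reference = 2, n_users = 5,
                         instructions = 1:6) {
  if (!(k %in% 2:6)) stop("k must be in 2..6, got ", k)
  if (!(reference %in% instructions)) stop("reference not in instruction set")
  if (n_users != 5) stop("the collaborative group design uses 5 users")
  non_ref <- sort(setdiff(instructions, reference))
  users <- LETTERS[seq_len(n_users)]
  subsets <- lapply(seq_len(n_users) - 1L, function(u) {
    lab <- (u + 0:(k - 2L)) %% length(non_ref)
    sort(c(reference, non_ref[lab + 1L]))
  })
  names(subsets) <- users
  structure(list(k = as.integer(k), reference = as.integer(reference),
                 users = users, subsets = subsets,
                 instructions = sort(instructions)),
            class = "allocation_scheme")
}

#' @export
print.allocation_scheme <- function(x, ...) {
  cat("<allocation_scheme> '", x$k, " Tasks', reference = ", x$reference,
      "\n", sep = "")
  for (u in x$users) {
    cat("  user ", u, ": {", paste(x$subsets[[u]], collapse = ", "), "}\n",
        sep = "")
  }
  invisible(x)
}

#' Collaborative modes induced by an allocation scheme
#'
#' One mode per system input instruction: users whose subset contains the
#' input instruction are assigned it; all other users are assigned the
#' reference instruction. The reference-instruction mode therefore assigns
#' the reference to all five users.
#'
#' @param scheme An `allocation_scheme`.
#' @return A list of six `collaborative_mode` objects (one per instruction,
#'   in instruction order), each with `mode_id`, `input_instruction`,
#'   `assignment` (named integer, user -> instruction performed).
#' @export
build_modes <- function(scheme) {
  stopifnot(inherits(scheme, "allocation_scheme"))
  lapply(scheme$instructions, function(instr) {
    assign <- vapply(scheme$users, function(u) {
      if (instr %in% scheme$subsets[[u]]) as.integer(instr) else scheme$reference
    }, integer(1))
    structure(list(mode_id = as.integer(instr),
                   input_instruction = as.integer(instr),
                   assignment = assign),
              class = "collaborative_mode")
  })
}

#' Assemble the six collaborative models from users' submodels
#'
#' For every collaborative mode, picks from each user's single-user model
#' the submodel whose target equals that user's assigned instruction. For
#' the feature-fusion method the returned models still need their fused
#' classifier trained with [train_feature_fusion()]; for decision fusion the
#' member submodels and their `lambda` weights are all that is needed.
#'
#' @param scheme An `allocation_scheme`.
#' @param user_models Named list (user -> list of `submodel` objects keyed
#'   by target instruction as character) covering each user's subset.
#' @param method `"decision"` or `"feature"` (stored for bookkeeping).
#' @return A list of six `collaborative_model` objects with `mode`,
#'   `members` (named list user -> `submodel`), `lambda` (named numeric),
#'   `method`, `fusion` (NULL until trained).
#' @export
assemble_models <- function(scheme, user_models,
                            method = c("decision", "feature")) {
  method <- match.arg(method)
  modes <- build_modes(scheme)
  lapply(modes, function(mode) {
    members <- lapply(scheme$users, function(u) {
      target <- mode$assignment[[u]]
      sm <- user_models[[u]][[as.character(target)]]
      if (is.null(sm)) {
        stop("user ", u, " has no submodel for instruction ", target)
      }
      if (sm$target != target) {
        stop("submodel target mismatch for user ", u, ": expected ", target,
             ", got ", sm$target)
      }
      sm
    })
    names(members) <- scheme$users
    structure(
      list(mode = mode, members = members,
           lambda = vapply(members, function(s) s$lambda, numeric(1)),
           method = method, fusion = NULL),
      class = "collaborative_model"
    )
  })
}

#' Export an allocation scheme as JSON
#'
#' @param scheme An `allocation_scheme`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
scheme_to_json <- function(scheme, path = NULL) {
  obj <- list(k = scheme$k, reference = scheme$reference,
              users = scheme$users, subsets = scheme$subsets)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
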