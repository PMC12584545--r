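# Internal helpers shared across the pipeline.
#
# A "feature block" is a tibble whose first column is `sample_id` and whose
# remaining columns are numeric features (rows = samples). Internally blocks
# are converted to matrices with sample_id rownames; all stages keep rows in
# the order of the first block and fail loudly on misalignment.

as_feature_matrix <- function(block, arg = "block") {
  if (is.matrix(block)) {
    if (is.null(rownames(block))) {
      abort(sprintf("`%s` matrix must carry sample ids as rownames", arg))
    }
    storage.mode(block) <- "double"
    return(block)
  }
  if (!is.data.frame(block)) {
    abort(sprintf("`%s` must be a data frame with a sample_id first column", arg))
  }
  if (!"sample_id" %in% names(block)) {
    abort(sprintf("`%s` has no `sample_id` column", arg))
  }
  ids <- as.character(block$sample_id)
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "duplicated sample_id in `%s`: %s", arg,
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  feat <- block[setdiff(names(block), "sample_id")]
  bad <- names(feat)[!vapply(feat, is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("non-numeric feature column(s) in `%s`: %s", arg,
                  paste(head(bad, 5L), collapse = ", ")))
  }
  m <- as.matrix(feat)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

as_feature_tibble <- function(m) {
  tibble::as_tibble(m, .name_repair = "minimal") |>
    dplyr::mutate(sample_id = rownames(m), .before = 1L)
}

check_survival <- function(survival, sample_ids = NULL) {
  if (!is.data.frame(survival) ||
      !all(c("sample_id", "time", "event") %in% names(survival))) {
    abort("`survival` must have columns sample_id, time, event")
  }
  if (any(!survival$event %in% c(0, 1))) abort("`event` must be 0/1")
  if (any(survival$time <= 0)) abort("survival times must be positive")
  if (!is.null(sample_ids)) {
    if (!identical(as.character(survival$sample_id), as.character(sample_ids))) {
      abort("survival rows are not aligned with the feature block sample order")
    }
  }
  invisible(survival)
}

check_blocks_aligned <- function(blocks) {
  mats <- lapply(seq_along(blocks), function(i) {
    as_feature_matrix(blocks[[i]], arg = sprintf("blocks[[%d]]", i))
  })
  ids <- rownames(mats[[1]])
  for (i in seq_along(mats)[-1]) {
    if (!identical(rownames(mats[[i]]), ids)) {
      abort("feature blocks do not share the same ordered sample ids")
    }
  }
  mats
}

is_standardized <- function(block) isTRUE(attr(block, "standardized"))

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so package functions never clobber user RNG.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# All permutations of 1..n (n <= 8 in practice: one column per permutation).
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    for (j in seq_len(ncol(sub))) {
      col <- col + 1L
      out[, col] <- c(i, rest[sub[, j]])
    }
  }
  out
}

# Relabel `labels` by the permutation of 1..k maximizing agreement with `ref`
# (exact assignment search on the k x k confusion matrix; k <= 8).
align_labels_to <- function(ref, labels, k) {
  conf <- matrix(0L, k, k)
  tab <- table(factor(labels, levels = seq_len(k)), factor(ref, levels = seq_len(k)))
  conf[seq_len(k), seq_len(k)] <- tab
  perms <- permutations(k)
  agree <- vapply(seq_len(ncol(perms)), function(j) {
    sum(conf[cbind(seq_len(k), perms[, j])])
  }, numeric(1))
  best <- perms[, which.max(agree)]
  best[labels]
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}
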