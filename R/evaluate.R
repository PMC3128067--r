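#' Construct confusion counts
#'
#' @param TP,FP,TN,FN,H non-negative integers; \code{H} is the total hit
#'   count over all secondary sequences.
#' @return a \linkS4class{ConfusionCounts}.
#' @export
ConfusionCounts <- function(TP, FP, TN, FN, H) {
  new("ConfusionCounts", TP = as.integer(TP), FP = as.integer(FP),
      TN = as.integer(TN), FN = as.integer(FN), H = as.integer(H))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d TN=%d FN=%d (H=%d hits)\n",
              object@TP, object@FP, object@TN, object@FN, object@H))
})

#' Confusion counts of a seed set on a dataset
#'
#' Runs \code{\link{groupHits}} over every group and aggregates: TP = hit
#' oligos, FP = hit non-oligos, TN = unhit non-oligos, FN = unhit oligos,
#' H = total hit count.
#'
#' @param seeds a \linkS4class{SeedSet} (or coercible).
#' @param dataset an \linkS4class{OligoDataset}.
#' @param bothStrands passed to \code{\link{groupHits}}.
#' @return a \linkS4class{ConfusionCounts}.
#' @export
confusionCounts <- function(seeds, dataset, bothStrands = FALSE) {
  stopifnot(is(dataset, "OligoDataset"))
  seeds <- .asSeedSet(seeds)
  tp <- fp <- tn <- fn <- h <- 0L
  for (grp in dataset@groups) {
    rep <- groupHits(seeds, grp, bothStrands = bothStrands)
    oligo <- secondaryLabels(grp) == "oligo"
    tp <- tp + sum(rep@hit & oligo)
    fp <- fp + sum(rep@hit & !oligo)
    tn <- tn + sum(!rep@hit & !oligo)
    fn <- fn + sum(!rep@hit & oligo)
    h <- h + rep@totalHits
  }
  ConfusionCounts(tp, fp, tn, fn, h)
}

#' @rdname seed-metrics
#' @export
setMethod("precision", "ConfusionCounts", function(x) {
  d <- x@TP + x@FP
  if (d == 0L) {
    message("precision undefined: no secondary was hit (TP + FP = 0)")
    return(NA_real_)
  }
  x@TP / d
})

#' @rdname seed-metrics
#' @export
setMethod("recall", "ConfusionCounts", function(x) {
  d <- x@TP + x@FN
  if (d == 0L) {
    message("recall undefined: dataset contains no oligos (TP + FN = 0)")
    return(NA_real_)
  }
  x@TP / d
})

#' @rdname seed-metrics
#' @export
setMethod("fScore", "ConfusionCounts", function(x) {
  p <- suppressMessages(precision(x))
  r <- suppressMessages(recall(x))
  if (is.na(p) || is.na(r)) {
    message("F-score undefined: precision or recall is undefined")
    return(NA_real_)
  }
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
})

#' @rdname seed-metrics
#' @export
setMethod("efficiency", "ConfusionCounts", function(x) {
  if (x@H == 0L) {
    message("efficiency undefined: the seed produced no hits (H = 0)")
    return(NA_real_)
  }
  x@TP / x@H
})

#' Evaluate every catalogued seed set on every dataset
#'
#' For each catalogue entry whose weight lies in \code{weights} and each
#' dataset, computes confusion counts and the four metrics. Requested
#' weights missing from the catalogue are skipped with a warning.
#'
#' @param catalog a \linkS4class{SeedCatalog}.
#' @param datasets a named list of \linkS4class{OligoDataset} (a single
#'   dataset is accepted).
#' @param weights integer vector of seed weights to evaluate (default
#'   7:20).
#' @return a data.frame with columns seed_type, k, weight, dataset, TP,
#'   FP, TN, FN, H, precision, recall, fscore, efficiency.
#' @export
sweepSeedCatalog <- function(catalog, datasets, weights = 7:20) {
  stopifnot(is(catalog, "SeedCatalog"))
  if (is(datasets, "OligoDataset"))
    datasets <- list(ds1 = datasets)
  if (is.null(names(datasets)))
    names(datasets) <- paste0("ds", seq_along(datasets))
  idx <- catalog@index
  if (!nrow(idx))
    stop("empty seed catalogue")
  missing <- setdiff(weights, idx$weight)
  if (length(missing))
    warning(sprintf("no catalogue entry for weight(s) %s; skipped",
                    paste(missing, collapse = ", ")))
  keep <- which(idx$weight %in% weights)
  rows <- vector("list", length(keep) * length(datasets))
  n <- 0L
  for (i in keep) {
    set <- catalog@sets[[idx$name[i]]]
    for (d in names(datasets)) {
      cc <- confusionCounts(set, datasets[[d]])
      n <- n + 1L
      rows[[n]] <- data.frame(
        seed_type = idx$seed_type[i], k = idx$k[i], weight = idx$weight[i],
        dataset = d, TP = cc@TP, FP = cc@FP, TN = cc@TN, FN = cc@FN,
        H = cc@H,
        precision = suppressMessages(precision(cc)),
        recall = suppressMessages(recall(cc)),
        fscore = suppressMessages(fScore(cc)),
        efficiency = suppressMessages(efficiency(cc)))
    }
  }
  out <- do.call(rbind, rows[seq_len(n)])
  rownames(out) <- NULL
  out
}

# Aggregate a sweep table to per-(type, weight) means across datasets.
.aggregateSweep <- function(table) {
  if (any(is.na(table$fscore))) {
    message("dropping sweep rows with undefined F-score from aggregation")
    table <- table[!is.na(table$fscore), , drop = FALSE]
  }
  split_by <- interaction(table$seed_type, table$weight, drop = TRUE)
  agg <- lapply(split(table, split_by), function(sub) {
    data.frame(seed_type = sub$seed_type[1L], k = sub$k[1L],
               weight = sub$weight[1L], n_datasets = nrow(sub),
               mean_fscore = mean(sub$fscore),
               sd_fscore = stats::sd(sub$fscore),
               mean_recall = mean(sub$recall),
               mean_efficiency = mean(sub$efficiency))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$seed_type, out$weight), , drop = FALSE]
}

#' Highest mean accuracy per seed type
#'
#' For each seed type, finds the weight maximizing the mean F-score across
#' datasets, reporting the mean, its standard deviation over datasets, and
#' the mean efficiency at that weight. Ties break toward the lower weight
#' (cheaper hashing at equal accuracy). A single dataset yields a standard
#' deviation of 0.
#'
#' @param table a sweep table from \code{\link{sweepSeedCatalog}}.
#' @return a data.frame with one row per seed type, ordered by increasing
#'   mean F-score.
#' @export
bestAccuracy <- function(table) {
  agg <- .aggregateSweep(table)
  agg$sd_fscore[is.na(agg$sd_fscore)] <- 0
  best <- lapply(split(agg, agg$seed_type), function(sub) {
    sub <- sub[order(sub$weight), , drop = FALSE]
    sub[which.max(sub$mean_fscore), , drop = FALSE]
  })
  out <- do.call(rbind, best)
  rownames(out) <- NULL
  out[order(out$mean_fscore), , drop = FALSE]
}

#' Best accuracy under a recall lower bound
#'
#' For oligo design a very high recall is required, so seeds are also
#' ranked after imposing a lower bound on the mean recall: for each bound
#' and each seed type, only weights whose mean recall reaches the bound
#' are considered, and the best mean F-score among them (with its
#' efficiency) is reported. Types with no qualifying weight yield NA rows.
#'
#' @param table a sweep table from \code{\link{sweepSeedCatalog}}.
#' @param bounds vector of recall lower bounds in (0, 1]; default
#'   \code{seq(0.86, 0.99, by = 0.01)}.
#' @return a data.frame with columns bound, seed_type, k, weight,
#'   mean_fscore, mean_efficiency (weight and metrics NA when no seed of
#'   the type attains the bound).
#' @export
boundedRecall <- function(table, bounds = seq(0.86, 0.99, by = 0.01)) {
  stopifnot(all(bounds > 0), all(bounds <= 1))
  agg <- .aggregateSweep(table)
  types <- unique(agg$seed_type)
  rows <- list()
  for (b in bounds) {
    for (ty in types) {
      sub <- agg[agg$seed_type == ty & agg$mean_recall >= b, , drop = FALSE]
      rows[[length(rows) + 1L]] <- if (nrow(sub)) {
        sub <- sub[order(sub$weight), , drop = FALSE]
        i <- which.max(sub$mean_fscore)
        data.frame(bound = b, seed_type = ty, k = sub$k[i],
                   weight = sub$weight[i], mean_fscore = sub$mean_fscore[i],
                   mean_efficiency = sub$mean_efficiency[i])
      } else {
        data.frame(bound = b, seed_type = ty, k = NA_integer_,
                   weight = NA_integer_, mean_fscore = NA_real_,
                   mean_efficiency = NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
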