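test_that("topics follow the Topic_<ABBREV> naming convention", {
  t <- create_topics(c("patient_monitor", "ventilator"))
  expect_identical(t$name, c("Topic_PM", "Topic_VEN"))
  expect_identical(create_topics("his")$name, "Topic_HIS")
  expect_identical(create_topics("ai")$name, "Topic_AI")
  expect_error(create_topics(character()), class = "icufusion_validation_error")
  expect_error(create_topics(c("his", "his")), class = "icufusion_validation_error")
})

test_that("partition assignment is deterministic and balanced over random keys", {
  cl <- make_cluster(3, create_topics(c("patient_monitor")))
  expect_identical(
    as.character(assign_partition("dev-42", "Topic_PM", cl)),
    as.character(assign_partition("dev-42", "Topic_PM", cl))
  )
  keys <- sprintf("key-%05d", seq_len(10000))
  nodes <- vapply(
    keys, function(k) as.character(assign_partition(k, "Topic_PM", cl)), ""
  )
  load <- table(nodes)
  expect_identical(length(load), 3L)
  expect_lt(max(load) / min(load), 1.5)
  expect_true(all(load >= 0.25 * mean(load)))
  # cluster with no live nodes refuses routing
  dead <- fail_node(fail_node(fail_node(cl, "node-1"), "node-2"), "node-3")
  expect_true(dead$down)
  expect_error(assign_partition("k", "Topic_PM", dead),
    class = "icufusion_cluster_down"
  )
})

test_that("node failure reroutes every partition and conserves messages", {
  cl <- make_cluster(3, create_topics(c("patient_monitor", "ventilator")))
  for (i in 1:100) {
    topic <- if (i %% 2 == 0) "Topic_PM" else "Topic_VEN"
    cl <- enqueue(cl, topic, paste0("dev-", i %% 7), paste0("payload-", i))
  }
  cl <- fail_node(cl, "node-2")
  live <- cl$nodes$node_id[cl$nodes$live]
  expect_identical(sort(live), c("node-1", "node-3"))
  expect_true(all(cl$assignment$node_id %in% live))
  out <- drain(cl)
  expect_identical(nrow(out$messages), 100L)
  expect_identical(sort(out$messages$payload), sort(paste0("payload-", 1:100)))
  expect_error(fail_node(cl, "node-2"), class = "icufusion_validation_error")
})

test_that("message conservation holds under interleaved failure schedules", {
  cl <- make_cluster(4, create_topics("ventilator"))
  n_sent <- 0L
  for (round in 1:3) {
    for (i in 1:40) {
      cl <- enqueue(cl, "Topic_VEN", paste0("k", round, "-", i), "x")
      n_sent <- n_sent + 1L
    }
    cl <- fail_node(cl, paste0("node-", round))
    expect_true(all(
      cl$assignment$node_id %in% cl$nodes$node_id[cl$nodes$live]
    ))
  }
  expect_identical(nrow(drain(cl)$messages), n_sent)
})

test_that("stream aggregation reproduces exact unit-normalized totals", {
  stats <- aggregate_stream_stats(icu_device_inventory())
  expect_equal(stats$total_mbps, 65.664)
  expect_identical(stats$total_mbps_rounded, 65.66)
  expect_equal(stats$total_tb_per_year, 21.7368)
  expect_identical(stats$total_tb_rounded, 22)
  # order independence
  inv <- icu_device_inventory()
  shuffled <- inv[c(4, 2, 5, 1, 3), ]
  expect_equal(aggregate_stream_stats(shuffled), stats)
  # empty inventory sums to zero
  expect_equal(aggregate_stream_stats(inv[0, ])$total_mbps, 0)
  inv$rate[1] <- -1
  expect_error(aggregate_stream_stats(inv), class = "icufusion_validation_error")
})

test_that("delay simulator matches the M/M/1 closed form at one node", {
  d <- simulate_delay(1, 1, 0.5, 1, n_messages = 20000, seed = 2)
  expect_lt(abs(d$mean_delay - 2.0), 3 * d$se)
  expect_error(simulate_delay(1, 1, 1.2, 1), class = "icufusion_unstable")
})

test_that("expected delay is monotone non-increasing in cluster size", {
  prof <- delay_profile(c(1, 3), 5, 0.1, 1, n_messages = 20000, seed = 3)
  d1 <- prof[prof$n_nodes == 1, ]
  d3 <- prof[prof$n_nodes == 3, ]
  expect_lte(d3$mean_delay, d1$mean_delay + 3 * sqrt(d1$se^2 + d3$se^2))
  expect_lt(d3$utilization, d1$utilization)
})
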