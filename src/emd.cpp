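#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>

// Exact Earth Mover's Distance between two discrete weighted point sets,
// solved as a minimum-cost flow on the bipartite transport graph
// (successive shortest paths with Dijkstra + node potentials; all arc
// costs are nonnegative so reduced costs stay nonnegative throughout).
//
// a: supplies (length n), b: demands (length m), both summing to the same
// total mass; cost: n x m ground-distance matrix. Returns the optimal
// transport cost sum_ij f_ij * cost_ij.

namespace {

struct Edge {
    int to;
    double cap;
    double cost;
    int rev;  // index of reverse edge in graph[to]
};

class MinCostFlow {
public:
    explicit MinCostFlow(int n) : graph_(n), n_(n) {}

    void add_edge(int from, int to, double cap, double cost) {
        graph_[from].push_back({to, cap, cost, static_cast<int>(graph_[to].size())});
        graph_[to].push_back({from, 0.0, -cost, static_cast<int>(graph_[from].size()) - 1});
    }

    // send `flow` units from s to t, return total cost
    double solve(int s, int t, double flow) {
        const double INF = std::numeric_limits<double>::infinity();
        double total = 0.0;
        std::vector<double> pot(n_, 0.0), dist(n_);
        std::vector<int> pv(n_), pe(n_);
        const double eps = flow * 1e-12;

        while (flow > eps) {
            // Dijkstra with reduced costs
            std::fill(dist.begin(), dist.end(), INF);
            dist[s] = 0.0;
            using Node = std::pair<double, int>;
            std::priority_queue<Node, std::vector<Node>, std::greater<Node>> pq;
            pq.push({0.0, s});
            while (!pq.empty()) {
                auto [d, u] = pq.top(); pq.pop();
                if (d > dist[u] + 1e-15) continue;
                for (int i = 0; i < static_cast<int>(graph_[u].size()); ++i) {
                    const Edge& e = graph_[u][i];
                    if (e.cap <= eps) continue;
                    const double nd = d + e.cost + pot[u] - pot[e.to];
                    if (nd < dist[e.to] - 1e-15) {
                        dist[e.to] = nd;
                        pv[e.to] = u;
                        pe[e.to] = i;
                        pq.push({nd, e.to});
                    }
                }
            }
            if (dist[t] == INF) break;  // no augmenting path (mass imbalance)
            for (int v = 0; v < n_; ++v)
                if (dist[v] < INF) pot[v] += dist[v];

            double push = flow;
            for (int v = t; v != s; v = pv[v])
                push = std::min(push, graph_[pv[v]][pe[v]].cap);
            for (int v = t; v != s; v = pv[v]) {
                Edge& e = graph_[pv[v]][pe[v]];
                e.cap -= push;
                graph_[v][e.rev].cap += push;
                total += push * e.cost;
            }
            flow -= push;
        }
        return total;
    }

private:
    std::vector<std::vector<Edge>> graph_;
    int n_;
};

}  // namespace

// [[Rcpp::export]]
double emd_cpp(const Rcpp::NumericVector& a,
               const Rcpp::NumericVector& b,
               const Rcpp::NumericMatrix& cost)
{
    const int n = a.size(), m = b.size();
    if (cost.nrow() != n || cost.ncol() != m)
        Rcpp::stop("cost matrix dimensions do not match the weight vectors");

    // nodes: 0 = source, 1..n = supplies, n+1..n+m = demands, n+m+1 = sink
    MinCostFlow mcf(n + m + 2);
    const int S = 0, T = n + m + 1;
    double total = 0.0;
    for (int i = 0; i < n; ++i) {
        mcf.add_edge(S, 1 + i, a[i], 0.0);
        total += a[i];
    }
    for (int j = 0; j < m; ++j)
        mcf.add_edge(1 + n + j, T, b[j], 0.0);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < m; ++j)
            mcf.add_edge(1 + i, 1 + n + j, std::numeric_limits<double>::infinity(),
                         cost(i, j));

    return mcf.solve(S, T, total);
}
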