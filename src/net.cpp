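// Minimal POSIX socket layer. Base R connections cannot disable Nagle's
// algorithm and have no UDP, both of which the transport contract needs:
// ring messages must leave immediately (batching happens at the
// application layer, one bundle per frame per link).
#include <Rcpp.h>
#include <arpa/inet.h>
#include <netinet/in.h>
#include <netinet/tcp.h>
#include <sys/socket.h>
#include <poll.h>
#include <unistd.h>
#include <fcntl.h>
#include <cstring>
#include <cerrno>
using namespace Rcpp;

static void set_nodelay(int fd) {
  int one = 1;
  setsockopt(fd, IPPROTO_TCP, TCP_NODELAY, &one, sizeof(one));
}

static sockaddr_in make_addr(const std::string &host, int port) {
  sockaddr_in addr;
  std::memset(&addr, 0, sizeof(addr));
  addr.sin_family = AF_INET;
  addr.sin_port = htons((uint16_t)port);
  if (inet_pton(AF_INET, host.c_str(), &addr.sin_addr) != 1)
    stop("invalid IPv4 address '%s'", host.c_str());
  return addr;
}

// [[Rcpp::export(name = ".nr_tcp_listen")]]
List nr_tcp_listen(std::string host, int port) {
  int fd = socket(AF_INET, SOCK_STREAM, 0);
  if (fd < 0) stop("socket: %s", strerror(errno));
  int one = 1;
  setsockopt(fd, SOL_SOCKET, SO_REUSEADDR, &one, sizeof(one));
  sockaddr_in addr = make_addr(host, port);
  if (bind(fd, (sockaddr *)&addr, sizeof(addr)) < 0) {
    int e = errno; close(fd);
    stop("bind: %s", strerror(e));
  }
  if (listen(fd, 8) < 0) {
    int e = errno; close(fd);
    stop("listen: %s", strerror(e));
  }
  socklen_t len = sizeof(addr);
  getsockname(fd, (sockaddr *)&addr, &len);
  return List::create(_["fd"] = fd, _["port"] = (int)ntohs(addr.sin_port));
}

// [[Rcpp::export(name = ".nr_tcp_accept")]]
int nr_tcp_accept(int listen_fd, int timeout_ms) {
  pollfd p{listen_fd, POLLIN, 0};
  int r = poll(&p, 1, timeout_ms);
  if (r <= 0) return -1;
  int fd = accept(listen_fd, nullptr, nullptr);
  if (fd < 0) return -1;
  set_nodelay(fd);
  return fd;
}

// [[Rcpp::export(name = ".nr_tcp_connect")]]
int nr_tcp_connect(std::string host, int port, int timeout_ms) {
  int fd = socket(AF_INET, SOCK_STREAM, 0);
  if (fd < 0) return -1;
  sockaddr_in addr = make_addr(host, port);
  int flags = fcntl(fd, F_GETFL, 0);
  fcntl(fd, F_SETFL, flags | O_NONBLOCK);
  int r = connect(fd, (sockaddr *)&addr, sizeof(addr));
  if (r < 0 && errno != EINPROGRESS) { close(fd); return -1; }
  if (r < 0) {
    pollfd p{fd, POLLOUT, 0};
    if (poll(&p, 1, timeout_ms) <= 0) { close(fd); return -1; }
    int err = 0; socklen_t elen = sizeof(err);
    getsockopt(fd, SOL_SOCKET, SO_ERROR, &err, &elen);
    if (err != 0) { close(fd); return -1; }
  }
  fcntl(fd, F_SETFL, flags); // back to blocking
  set_nodelay(fd);
  return fd;
}

// [[Rcpp::export(name = ".nr_send")]]
int nr_send(int fd, RawVector data) {
  size_t total = 0, n = data.size();
  const char *buf = (const char *)RAW(data);
  while (total < n) {
    ssize_t w = send(fd, buf + total, n - total, MSG_NOSIGNAL);
    if (w < 0) {
      if (errno == EINTR) continue;
      return -1;
    }
    total += (size_t)w;
  }
  return (int)total;
}

// Read up to max_bytes; waits up to timeout_ms for the first byte.
// Returns a raw vector (possibly empty on timeout); NULL on closed peer.
// [[Rcpp::export(name = ".nr_recv")]]
SEXP nr_recv(int fd, int max_bytes, int timeout_ms) {
  pollfd p{fd, POLLIN, 0};
  int r = poll(&p, 1, timeout_ms);
  if (r <= 0) return RawVector(0);
  std::vector<char> buf(max_bytes);
  ssize_t got = recv(fd, buf.data(), max_bytes, 0);
  if (got == 0) return R_NilValue; // orderly shutdown
  if (got < 0) return RawVector(0);
  RawVector out(got);
  std::memcpy(RAW(out), buf.data(), got);
  return out;
}

// [[Rcpp::export(name = ".nr_close")]]
void nr_close(int fd) { if (fd >= 0) close(fd); }

// [[Rcpp::export(name = ".nr_udp_bind")]]
List nr_udp_bind(std::string host, int port) {
  int fd = socket(AF_INET, SOCK_DGRAM, 0);
  if (fd < 0) stop("socket: %s", strerror(errno));
  sockaddr_in addr = make_addr(host, port);
  if (bind(fd, (sockaddr *)&addr, sizeof(addr)) < 0) {
    int e = errno; close(fd);
    stop("bind: %s", strerror(e));
  }
  socklen_t len = sizeof(addr);
  getsockname(fd, (sockaddr *)&addr, &len);
  return List::create(_["fd"] = fd, _["port"] = (int)ntohs(addr.sin_port));
}

// [[Rcpp::export(name = ".nr_udp_send")]]
int nr_udp_send(std::string host, int port, RawVector data) {
  int fd = socket(AF_INET, SOCK_DGRAM, 0);
  if (fd < 0) return -1;
  sockaddr_in addr = make_addr(host, port);
  ssize_t w = sendto(fd, RAW(data), data.size(), 0, (sockaddr *)&addr,
                     sizeof(addr));
  close(fd);
  return (int)w;
}

// One datagram (or empty raw on timeout).
// [[Rcpp::export(name = ".nr_udp_recv")]]
RawVector nr_udp_recv(int fd, int max_bytes, int timeout_ms) {
  pollfd p{fd, POLLIN, 0};
  int r = poll(&p, 1, timeout_ms);
  if (r <= 0) return RawVector(0);
  std::vector<char> buf(max_bytes);
  ssize_t got = recvfrom(fd, buf.data(), max_bytes, 0, nullptr, nullptr);
  if (got < 0) return RawVector(0);
  RawVector out(got);
  std::memcpy(RAW(out), buf.data(), got);
  return out;
}
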