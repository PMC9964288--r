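park_id,name,area_ha,bank,category
NWMC,National Water Museum of China,129.8,south,comprehensive
QCP,Qianjiang Century Park,62,south,comprehensive
YWP,Yanjiang Wetland Park,33.2,north,special
BP,Binjiang Park,29.07,south,linear
CP,CBD Park,26,north,comprehensive
YP,Yanjiang Park,19.06,south,linear
QEP,Qianjiang Ecological Park,18,north,comprehensive
BTP,Baita Park,15.66,north,comprehensive
LCP,Liuheta Cultural Park,10.8,north,special
WRP,Wenyan Riverside Park,3.98,south,comprehensive
WP,Wangjiang Park,3.32,north,roadside
UBP,Urban Balcony Park,2.81,north,comprehensive
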