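char_code,name,type,method,states
char1,First leaf: shape of tip,PQ,VG,pointed(1);pointed to rounded(2);rounded(3)
char2,Seedling: leaf color,PQ,VG,yellow-green(1);green(2);light purple(3);purple(4)
char3,Seedling: leaf sheath color,PQ,VG,green(1);light purple(2);medium purple(3)
char4,Seedling: growth habit,PQ,VG,upright(1);semi-upright(2);spreading(3);drooping(4)
char5,Seedling: anthocyanin shows color in leaf midrib,QN,VG,absent or weak(1);medium(2);strong(3)
char6,Time of heading,QN,MG,very early(1);early(3);medium(5);late(7);very late(9)
char7,Plant: growth habit,PQ,VG,upright(1);semi-upright(2);spreading(3);drooping(4)
char8,Panicle: length of bristles,QN,VG,short(3);medium(5);long(7)
char9,Panicle: bristles color,PQ,VG,green(1);yellow(2);purple(3)
char10,Anther: color,PQ,VG,white(1);yellow(2);brown(3)
char11,Flag leaf: length of blade,QN,MS/MG,short(1);medium(3);long(5)
char12,Flag leaf: width of blade,QN,MS/MG,narrow(1);medium(3);broad(5)
char13,Panicle: color of glume,PQ,VG,yellow-green(1);green(2);red(3);light purple(4);medium purple(5)
char14,Stem: length,QN,MS/MG,very short(1);short(3);medium(5);long(7);very long(9)
char15,Stem: diameter,QN,MS/MG,narrow(3);medium(5);broad(7)
char16,Plant: color,PQ,VG,yellow(1);green(2);light purple(3);medium purple(4)
char17,Plant: number of elongated internodes,QN,MG,few(1);medium(3);many(5)
char18,Plant: number of culms per panicle,QN,MS,few(1);medium(3);many(5)
char19,Panicle neck: attitude,PQ,VG,straight(1);medium curve(2);strong curve(3);claw(4)
char20,Panicle neck: length,QN,MS,short(3);medium(5);long(7)
char21,Panicle: type,PQ,VG,conical(1);spindle(2);cylindrical(3);club(4);duck mouth(5);cat foot(6);branched(7)
char22,Panicle: length,QN,MG,very short(1);short(3);medium(5);long(7);very long(9)
char23,Panicle: diameter,QN,MS,narrow(3);medium(5);broad(7)
char24,Panicle: density,QN,VG,lax(1);lax to medium(2);medium(3);medium to dense(4);dense(5)
char25,Panicle: single-grain number,QN,MG,very few(1);few(3);medium(5);many(7);very many(9)
char26,Panicle: single panicle weight,QN,MS,very low(1);low(3);medium(5);high(7);very high(9)
char27,Panicle: grain yield per panicle,QN,MS,low(1);medium(2);high(3)
char28,1000 grain weight,QN,MG,low(1);medium(2);high(3)
char29,Grain: shape,PQ,VG,narrow ovate(1);medium ovate(2);circular(3)
char30,Grain: color,PQ,VG,white(1);yellow(2);red(3);brown(4);gray(5);black(6)
char31,Dehusked grain: color (not polished),PQ,VG,white(1);gray-green(2);light yellow(3);medium yellow(4);gray(5)
char32,Endosperm: type,QL,VG,waxy(1);non-waxy(2)
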